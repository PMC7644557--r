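# Golden example sentences for each rigor criterion and resource class,
# with the label their row carries. Each must be detected with that label.

golden_criterion_sentences <- function() {
  list(
    IRB = c(
      "All human work was conducted under human subjects protocols approved by the Stanford Institutional Review Board (IRB), the University of Michigan UM-IRBMED, and the ethical committee of d'Ile de France II.",
      "The trial was approved by the NRES committee London-South East."
    ),
    CONSENT = c(
      "Written informed consent was obtained from parents of all participating children and oral assent was obtained from 7-year-olds.",
      "All infants were enrolled with informed parental permission under a protocol that was reviewed and approved by the Institutional Review Boards of the respective study sites."
    ),
    IACUC = c(
      "All animal experiments were performed in accordance with relevant guidelines and regulations and were approved by the University of Pennsylvania Institutional Animal Care and Use Committee (IACUC).",
      "All animals used in this study were treated in accordance with UK animal (scientific procedures) legislation and under the appropriate project licenses, national and local ethical approval."
    ),
    RANDOMIZATION = c(
      "Animals were assigned to experimental groups using simple randomization.",
      "Communication with schools, and elicitation of willingness to participate, was conducted before the village-level randomization took place."
    ),
    BLINDING = c(
      "Responses were then scored by an experimenter blinded to injection condition and experimental cohort.",
      "All the analysis was performed by a person unaware of the experimental question."
    ),
    POWER = c(
      "Sample size was based on estimations by power analysis with a level of significance of 0.05 and a power of 0.9.",
      "Sample size calculation was done for the primary aim of this study, i.e., FMD, as reported previously."
    ),
    SEX = c(
      "Six healthy adult rhesus macaques (Macaca mulatta) of Chinese origin (4-8 kg, three males and three females, 4-8 years old) were inoculated intramuscularly (i.m.) with 1,000 pfu of EBOV Makona strain.",
      "In each session, the behavior of each mother was recorded every 2 min."
    ),
    CELL_AUTH = c(
      "MOLM-14 cells were authenticated by STR profiling and flow cytometry.",
      "All cell lines were obtained from ATCC, tested negative for mycoplasma, and their identity was verified by short tandem repeat analysis (Promega GenePrint 10 system)."
    ),
    CELL_CONTAM = c(
      "All cell lines were obtained from ATCC and tested negative for mycoplasma contamination.",
      "All cell lines were confirmed to be mycoplasma free using a PCR-based detection strategy with positive and negative controls."
    )
  )
}

golden_resource_sentences <- function() {
  list(
    ANTIBODY = c(
      "ATF3 antibody (Santa Cruz Biotechnology) was used at 1:2000.",
      "Slices were then washed (3x) and placed in PBS containing the following: 1% (vol/vol) normal goat serum, 1% (vol/vol) BSA, 0.25% (vol/vol) Triton X-100, and mouse monoclonal anti-5.8S rRNA, clone Y10b at 1:500 (Abcam, ab37144, RRID: AB_777714) overnight at 4C."
    ),
    ORGANISM = c(
      "Adult (10-12 weeks; 25-30g) male C57BL/6 and TH-Cre mice were group-housed until surgery.",
      "To generate PIP821bpD the following sgRNA was generated 5'-GCAGGAGGAGGTACAGCGGG-3' and cloned into pU6-2-BbsI-gRNA (DGRC #1363) and then subsequently injected into w1118; vas-Cas9 (RRID:BDSC_51324, rainbow transgenics).",
      "The transgenic lines used in this study were Tg(kdrl:EGFP)s843 (Jin et al., 2005), Tg(lyve1b:dsRed2)nz101, Tg(lyve1b:EGFP)nz150 (Okuda et al., 2012) and Tg(-8.mpx:KalTA4)gl28."
    ),
    CELL_LINE = c(
      "The lung cancer cell line, H1299, was obtained from the American Tissue Culture Collection (Manassas, VA).",
      "J774A.1 murine monocytes and macrophages (ATCC, number TIB-67) were cultured at 37C in a humidified atmosphere in RPMI medium supplemented with 10% (v/v) heat-inactivated fetal bovine serum, penicillin (100 IU/mL), streptomycin (100 ug/mL), and amphotericin B (250 ng/mL)."
    ),
    PLASMID = c(
      "The constructions were prepared using the vector pSpCas9(BB)-2A-Puro (PX459) V2.0, which was a gift from Feng Zhang (Addgene plasmid #62988; RRID: Addgene_62988).",
      "For expression in HEK293 cells, INF2 was first subcloned into pGADT7.3 (BspEI/XmaI-XhoI) and then into pEGFP-C3 (EcoRI-SalI)."
    ),
    OLIGO = c(
      "Primers used were GRHL2-1-424-F (TATATAGGATCCATGTCACAAGAGTCGGACAA) and GRHL2-1-424-R (ATATAAAGATCTTTTTCTTTCTGCTCCTTTGT)."
    ),
    SOFTWARE = c(
      "ImageJ was used to process and analyze raw images.",
      "All simulations were performed using the NEURON simulation environment (Carnevale and Hines, 2006)."
    )
  )
}

doc_from_text <- function(text, doc_id = "d1", journal = "Test Journal",
                          issn = "0000-0000", year = 2019L) {
  new_document(doc_id, journal, issn, year, text)
}

# Minimal JATS article builder.
jats_article <- function(sections, journal = "Test Journal",
                         issn = "1234-5678", year = 2018,
                         doc_id = "PMC0001") {
  secs <- paste(vapply(sections, function(s) {
    st <- if (is.null(s$sec_type)) "" else sprintf(' sec-type="%s"', s$sec_type)
    paras <- paste(sprintf("<p>%s</p>", s$paragraphs), collapse = "")
    title <- if (is.null(s$title)) "" else sprintf("<title>%s</title>", s$title)
    sprintf("<sec%s>%s%s</sec>", st, title, paras)
  }, character(1)), collapse = "")
  sprintf(
    '<?xml version="1.0"?>
<article>
  <front>
    <journal-meta>
      <journal-title>%s</journal-title>
      <issn>%s</issn>
    </journal-meta>
    <article-meta>
      <article-id>%s</article-id>
      <pub-date><year>%d</year></pub-date>
    </article-meta>
  </front>
  <body>%s</body>
</article>', journal, issn, doc_id, year, secs)
}

all_one_prevalence <- function() {
  stats::setNames(rep(1, 9),
                  c("IRB", "CONSENT", "IACUC", "RANDOMIZATION", "BLINDING",
                    "POWER", "SEX", "CELL_AUTH", "CELL_CONTAM"))
}

all_zero_prevalence <- function() {
  stats::setNames(rep(0, 9), names(all_one_prevalence()))
}

saturated_resource_config <- function(identifiable_prob = 1) {
  tibble::tibble(
    resource_type = c("ANTIBODY", "ORGANISM", "CELL_LINE", "SOFTWARE",
                      "PLASMID", "OLIGO"),
    mean_mentions = c(1, 1, 1, 1, 0, 0),
    identifiable_prob = identifiable_prob
  )
}
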