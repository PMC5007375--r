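# Shared toy fixtures built in code.

toy_markers <- function() {
  geno <- rbind(
    m_good = c(rep("A/A", 25), rep("A/B", 25)),
    m_skew = c(rep("A/A", 48), rep("A/B", 2)),
    m_miss = c(rep("A/A", 30), rep(NA, 20)),
    m_tri  = c(rep("A/A", 25), rep("A/C", 25)))
  colnames(geno) <- paste0("off", 1:50)
  structure(list(
    queen = c(m_good = "A/B", m_skew = "A/B", m_miss = "A/B",
              m_tri = "A/B", m_hom = "A/A"),
    geno = rbind(geno, m_hom = c(rep("A/A", 50))),
    info = NULL, truth = NULL), class = "marker_matrix")
}
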