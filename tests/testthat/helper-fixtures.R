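# small in-code fixture builders shared by the tests

toy_matrix <- function(values, unit = "raw_counts",
                       features = sprintf("f%d", seq_len(nrow(values))),
                       samples = sprintf("s%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(features, samples)
  expression_matrix(values, unit)
}

toy_cohort_files <- function(dir = tempfile("io_")) {
  dir.create(dir)
  m <- data.frame(feature_id = c("fA", "fB", "fC"),
                  s1 = c(2, 8, 0), s2 = c(1, 1, 3))
  write.table(m, file.path(dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ss <- data.frame(sample_id = c("s1", "s2"), mouse_id = c("m1", "m1"),
                   age_months = c(2, 18), fraction = c("EV", "fc"))
  write.table(ss, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  fs <- data.frame(feature_id = c("fA", "fB", "fC"),
                   rna_class = c("miRNA", "miRNA", "tRF"))
  write.table(fs, file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dir
}
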