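# In-code fixtures shared across test files.

# a minimal hand-built cohort: 2 infants x 4 samples, 4 OTUs
toy_cohort_tables <- function() {
  counts <- matrix(
    c(10, 5, 0, 1,
      8, 6, 1, 0,
      2, 9, 3, 0,
      1, 7, 5, 2,
      9, 1, 1, 4,
      7, 2, 2, 4,
      3, 3, 6, 3,
      1, 2, 9, 3),
    nrow = 8, byrow = TRUE,
    dimnames = list(paste0("S", 1:8), paste0("x", 1:4)))
  storage.mode(counts) <- "integer"
  taxonomy <- data.frame(
    otu_id = paste0("x", 1:4),
    domain = "Bacteria",
    phylum = c("Bacteroidetes", "Actinobacteria", "Firmicutes",
               "Proteobacteria"),
    class = "unclassified", order = "unclassified", family = "unclassified",
    genus = "unclassified", stringsAsFactors = FALSE)
  meta <- data.frame(
    sample_id = paste0("S", 1:8),
    infant_id = rep(c("A", "B"), each = 4),
    day_since_birth = c(1L, 5L, 9L, 14L, 2L, 6L, 10L, 15L),
    stringsAsFactors = FALSE)
  list(counts = counts, taxonomy = taxonomy, meta = meta)
}

write_toy_files <- function(dir = tempfile()) {
  dir.create(dir)
  tb <- toy_cohort_tables()
  cdf <- data.frame(sample_id = rownames(tb$counts), tb$counts,
                    check.names = FALSE)
  write.table(cdf, file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(tb$taxonomy, file.path(dir, "taxonomy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(tb$meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines("((x1:0.2,x2:0.3):0.1,(x3:0.4,x4:0.1):0.2);",
             file.path(dir, "tree.nwk"))
  dir
}

# small, fast simulation settings for unit tests
small_config <- function(n_infants = 4L, n_otus = 24L, sampling_rate = 0.15,
                         twin_pair = c(3L, 4L), late_starter = 0L, ...) {
  sim_config(n_infants = n_infants, n_otus = n_otus,
             sampling_rate = sampling_rate, twin_pair = twin_pair,
             late_starter = late_starter, ...)
}

# a random rooted tree whose tips match a composition matrix's columns
random_tip_tree <- function(k, seed) {
  set.seed(seed)
  tr <- ape::rcoal(k, tip.label = paste0("t", seq_len(k)))
  tr
}
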