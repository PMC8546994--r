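# Fixtures are built in code; nothing is read from disk except what the
# tests themselves write to tempdirs.

# A tiny hand-built dataset: 2 subjects, 3 omic layers, 1 static layer.
tiny_dataset <- function(n_times = 6) {
  tt <- seq(0, by = 14, length.out = n_times)
  mk <- function(seed) {
    set.seed(seed)
    vals <- matrix(stats::runif(3 * n_times, 0.1, 1), 3,
                   dimnames = list(c("A", "B", "C"), NULL))
    list(times = tt, values = vals)
  }
  omics_dataset(list(
    omics_layer("taxa", "taxon", TRUE, c("A", "B", "C"),
                list(s1 = mk(1), s2 = mk(2))),
    omics_layer("genes", "gene", TRUE, c("A", "B", "C"),
                list(s1 = mk(3), s2 = mk(4))),
    omics_layer("metabolites", "metabolite", TRUE, c("A", "B", "C"),
                list(s1 = mk(5), s2 = mk(6))),
    omics_layer("host_genes", "host_gene", FALSE, c("H1", "H2"),
                list(s1 = c(H1 = 0.3, H2 = -1), s2 = c(H1 = 1.2, H2 = 0)))))
}

small_sim <- function(seed = 42, n_subjects = 12, n_points = 12, ...) {
  generate(simulation_config(n_subjects = n_subjects, n_taxa = 4, n_genes = 3,
                             n_metabolites = 3, n_host_genes = 2,
                             n_points = n_points, seed = seed, ...))
}

sort_by_child <- function(e) {
  e[order(e$child_layer, e$child_feature, e$parent_layer, e$parent_feature,
          e$lag), , drop = FALSE]
}

edge_keys <- function(e) {
  paste(e$parent_layer, e$parent_feature, e$child_layer, e$child_feature,
        e$lag)
}

# Write a dataset's TSVs by hand into a dir; returns paths for read_dataset.
write_tiny_tsvs <- function(dir, shuffle = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(
    sample_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
    subject_id = c("s1", "s1", "s1", "s2", "s2", "s2"),
    time = c(0, 14, 28, 0, 15, 29),
    week = c(0, 2, 4, 0, 15 / 7, 29 / 7))
  tax <- data.frame(feature_id = c("A", "B"),
                    a2 = c(2, 2), a1 = c(1, 3), a3 = c(0, 4),
                    b1 = c(5, 5), b3 = c(1, 0), b2 = c(2, 8))
  if (!shuffle) tax <- tax[, c("feature_id", "a1", "a2", "a3", "b1", "b2", "b3")]
  mp <- file.path(dir, "metadata.tsv"); tp <- file.path(dir, "taxa.tsv")
  utils::write.table(meta, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tax, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(layers = c(taxa = tp), metadata = mp)
}
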