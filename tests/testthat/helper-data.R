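# fixture loaders and small record builders shared across test files

table3 <- function() {
  read_dataset(system.file("extdata", "table3_arvicola.csv",
                           package = "rodiso"))
}

table1_summary <- function() {
  utils::read.csv(system.file("extdata", "table1_incisor_summary.csv",
                              package = "rodiso"),
                  stringsAsFactors = FALSE)
}

table2_summary <- function() {
  utils::read.csv(system.file("extdata", "table2_bone_summary.csv",
                              package = "rodiso"),
                  stringsAsFactors = FALSE)
}

table4_counts <- function() {
  read_bootstrap_counts(system.file("extdata", "table4_bootstrap_counts.csv",
                                    package = "rodiso"))
}

# quick record builder: one row per element of the value vectors
make_records <- function(specimen_id, tissue, species = "Testus testus",
                         family = "other", d18O_co3 = NA_real_,
                         d18O_po4 = NA_real_, d13C = NA_real_) {
  specimen_records(data.frame(
    specimen_id = specimen_id, species = species, family = family,
    tissue = tissue, d18O_co3 = d18O_co3, d18O_po4 = d18O_po4,
    d13C = d13C, stringsAsFactors = FALSE))
}

# records carrying the seven published per-species summary means, one row
# per species, for summary-level reconstructions
records_from_summary <- function(summ, tissue) {
  make_records(specimen_id = paste0("S", seq_len(nrow(summ))),
               species = summ$species, family = summ$family,
               tissue = tissue, d18O_co3 = summ$d18O_co3_mean,
               d13C = summ$d13C_mean)
}
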