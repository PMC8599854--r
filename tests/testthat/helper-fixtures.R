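# Shared fixture builders. Everything is generated in code; no data files.

# a single variant row with sensible passing defaults, override any field
make_variant <- function(...) {
  v <- tibble::tibble(
    patient_id = "P01", region_id = "R1", chrom = "1", pos = 1000L,
    ref = "C", alt = "A", gene = "GENE0001", func_class = "nonsynonymous",
    t_depth = 100L, n_depth = 50L, t_alt = 10L, t_vaf = 0.10, n_vaf = 0,
    lod = 25, cadd = 10, popfreq_esp = 0, popfreq_1kg = 0, popfreq_exac = 0,
    tnc = "ACA>AAA")
  over <- list(...)
  for (nm in names(over)) v[[nm]] <- over[[nm]]
  v
}

make_variants <- function(...) dplyr::bind_rows(...)

# binary mutation matrix from a list of per-mutation presence vectors
make_matrix <- function(rows, regions = paste0("R", seq_along(rows[[1]]))) {
  m <- do.call(rbind, rows)
  rownames(m) <- paste0("m", seq_len(nrow(m)))
  colnames(m) <- regions
  m
}

make_clonotypes <- function(freqs, patient = "P01", region = "R1",
                            names = NULL, total = 1000,
                            input_cells = NA_real_) {
  names <- names %||% paste0("seq", seq_along(freqs))
  clonotype_table(patient, region,
                  tibble::tibble(rearrangement = names,
                                 templates = round(freqs * total),
                                 productive_freq = freqs / sum(freqs)),
                  total_templates = total, input_cells = input_cells)
}

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(simulation_config(n_patients = 4, seed = 42))
    }
    cache
  }
})
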