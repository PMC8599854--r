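# Cohort data model and delimited I/O.
#
# All files are tab-separated UTF-8 with "." for missing values; coordinates
# are 1-based inclusive throughout (MAF/SEG convention). The clinical table is
# CSV. Clonotype tables carry a two-line "#key=value" header with
# total_templates and input_cells before the column header.

VARIANT_COLS <- c("patient_id", "region_id", "chrom", "pos", "ref", "alt",
                  "gene", "func_class", "t_depth", "n_depth", "t_alt",
                  "t_vaf", "n_vaf", "lod", "cadd", "popfreq_esp",
                  "popfreq_1kg", "popfreq_exac", "tnc")
SEGMENT_COLS <- c("patient_id", "region_id", "chrom", "start", "end",
                  "log2", "a_count", "b_count")
CLINICAL_COLS <- c("patient_id", "os_months", "os_event", "stage", "age",
                   "sex", "smoking", "tumor_size_cm")
NEOANTIGEN_COLS <- c("patient_id", "chrom", "pos", "ref", "alt", "gene",
                     "peptide", "allele", "ic50_nM")
FUNC_CLASSES <- c("nonsynonymous", "frameshift", "stopgain", "stoploss",
                  "synonymous", "other")
NONSILENT_CLASSES <- c("nonsynonymous", "frameshift", "stopgain", "stoploss")

#' Reserved region identifier for tumor-adjacent lung repertoires
#' @return The string `"adjacent_lung"`.
#' @export
adjacent_lung_region <- function() "adjacent_lung"

variant_key <- function(v) {
  paste(v$patient_id, v$region_id, v$chrom, v$pos, v$ref, v$alt, sep = ":")
}
mutation_key <- function(v) {
  paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
}

#' Construct a clonotype table
#'
#' One TCR-beta repertoire for one sample (a tumor region or
#' `"adjacent_lung"`), as reported by immunoSEQ-style profiling: unique CDR3
#' rearrangements with template counts and productive frequencies, plus the
#' sample-level total template count and the input nucleated-cell estimate
#' from housekeeping-gene amplification.
#'
#' @param patient_id,region_id Sample identity.
#' @param clones Tibble with columns `rearrangement`, `templates`,
#'   `productive_freq`.
#' @param total_templates Total TCR-beta templates in the sample.
#' @param input_cells Estimated nucleated cells assayed (NA if unknown).
#' @return An object of class `clonotype_table`.
#' @export
clonotype_table <- function(patient_id, region_id, clones,
                            total_templates = sum(clones$templates),
                            input_cells = NA_real_) {
  clones <- tibble::as_tibble(clones)
  stopifnot(all(c("rearrangement", "templates", "productive_freq")
                %in% names(clones)))
  structure(
    list(patient_id = patient_id, region_id = region_id,
         clones = clones,
         total_templates = as.numeric(total_templates),
         input_cells = as.numeric(input_cells)),
    class = "clonotype_table"
  )
}

#' @export
print.clonotype_table <- function(x, ...) {
  cat(sprintf("<clonotype_table> %s / %s: %d rearrangements, %g templates\n",
              x$patient_id, x$region_id, nrow(x$clones), x$total_templates))
  invisible(x)
}

#' Construct a tumor bundle
#'
#' All per-patient data for one multi-region-sequenced tumor: somatic variant
#' calls, allele-specific copy-number segments, per-region purity/ploidy,
#' class-I HLA genotype with binned allele-specific copy estimates, predicted
#' neoantigens, the clinical record, and TCR repertoires.
#'
#' @param patient_id Patient identifier.
#' @param regions Character vector of tumor region identifiers.
#' @param variants,segments,neoantigens Tibbles in the documented column
#'   layouts (may be empty).
#' @param samples Tibble `region_id`, `purity`, `ploidy`.
#' @param hla_genotype Character vector of six class-I alleles (A/B/C x2).
#' @param hla_allele_cn Tibble `region_id`, `allele`, `bin`, `cn` of binned
#'   allele-specific copy estimates.
#' @param clinical One-row tibble with `os_months`, `os_event`, `stage`,
#'   `age`, `sex`, `smoking`, `tumor_size_cm`.
#' @param repertoires List of [clonotype_table()] objects.
#' @return An object of class `tumor_bundle`.
#' @export
tumor_bundle <- function(patient_id, regions, variants = empty_variants(),
                         segments = empty_segments(), samples = NULL,
                         hla_genotype = character(),
                         hla_allele_cn = empty_hla_cn(),
                         neoantigens = empty_neoantigens(),
                         clinical = NULL, repertoires = list()) {
  if (is.null(samples)) {
    samples <- tibble::tibble(region_id = regions, purity = NA_real_,
                              ploidy = NA_real_)
  }
  structure(
    list(patient_id = patient_id, regions = regions,
         variants = tibble::as_tibble(variants),
         segments = tibble::as_tibble(segments),
         samples = tibble::as_tibble(samples),
         hla_genotype = hla_genotype,
         hla_allele_cn = tibble::as_tibble(hla_allele_cn),
         neoantigens = tibble::as_tibble(neoantigens),
         clinical = if (is.null(clinical)) NULL else tibble::as_tibble(clinical),
         repertoires = setNames(repertoires, vapply(
           repertoires, function(tb) tb$region_id, character(1)))),
    class = "tumor_bundle"
  )
}

#' @export
print.tumor_bundle <- function(x, ...) {
  cat(sprintf(
    "<tumor_bundle> %s: %d region(s), %d variant rows, %d segments, %d repertoire(s)\n",
    x$patient_id, length(x$regions), nrow(x$variants), nrow(x$segments),
    length(x$repertoires)))
  invisible(x)
}

empty_variants <- function() {
  tibble::tibble(patient_id = character(), region_id = character(),
                 chrom = character(), pos = integer(), ref = character(),
                 alt = character(), gene = character(),
                 func_class = character(), t_depth = integer(),
                 n_depth = integer(), t_alt = integer(), t_vaf = double(),
                 n_vaf = double(), lod = double(), cadd = double(),
                 popfreq_esp = double(), popfreq_1kg = double(),
                 popfreq_exac = double(), tnc = character())
}
empty_segments <- function() {
  tibble::tibble(patient_id = character(), region_id = character(),
                 chrom = character(), start = double(), end = double(),
                 log2 = double(), a_count = integer(), b_count = integer())
}
empty_neoantigens <- function() {
  tibble::tibble(patient_id = character(), chrom = character(),
                 pos = integer(), ref = character(), alt = character(),
                 gene = character(), peptide = character(),
                 allele = character(), ic50_nM = double())
}
empty_hla_cn <- function() {
  tibble::tibble(region_id = character(), allele = character(),
                 bin = integer(), cn = double())
}

#' Construct a cohort from tumor bundles
#' @param bundles List of [tumor_bundle()] objects.
#' @param config Optional named list of configuration values, kept for
#'   provenance hashing by [write_results()].
#' @return An object of class `ith_cohort` (a named list of bundles).
#' @export
ith_cohort <- function(bundles, config = list()) {
  names(bundles) <- vapply(bundles, function(b) b$patient_id, character(1))
  structure(list(bundles = bundles, config = config), class = "ith_cohort")
}

#' @export
print.ith_cohort <- function(x, ...) {
  cat(sprintf("<ith_cohort> %d patient(s): %s\n", length(x$bundles),
              paste(names(x$bundles), collapse = ", ")))
  invisible(x)
}

#' Combined variant table of a cohort
#' @param cohort An `ith_cohort`.
#' @return Tibble of all variant rows across patients.
#' @export
cohort_variants <- function(cohort) {
  dplyr::bind_rows(lapply(cohort$bundles, function(b) b$variants))
}

#' Combined clinical table of a cohort
#' @param cohort An `ith_cohort`.
#' @return Tibble of clinical records (one row per patient with a record).
#' @export
cohort_clinical <- function(cohort) {
  dplyr::bind_rows(lapply(cohort$bundles, function(b) b$clinical))
}

# ---- writing ---------------------------------------------------------------

# Exact text round-trip for doubles: 17 significant digits are sufficient to
# reproduce any IEEE double bit-for-bit on re-parse.
write_tsv_exact <- function(df, path, append = FALSE, col_names = !append) {
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::where(is.double),
    function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))))
  readr::write_tsv(df, path, na = ".", append = append,
                   col_names = col_names)
}


clonotype_file_name <- function(tab) {
  sprintf("%s_%s.tsv", tab$patient_id, tab$region_id)
}

#' Write a cohort to its delimited on-disk dialects
#'
#' Emits `variants.tsv`, `segments.tsv`, `samples.tsv`, `clinical.csv`,
#' `neoantigens.tsv`, `hla_genotypes.tsv`, `hla_allele_cn.tsv` and one
#' clonotype TSV per repertoire under `clonotypes/`. Tab-separated, UTF-8,
#' `"."` for missing; coordinates 1-based inclusive.
#'
#' @param cohort An `ith_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bs <- cohort$bundles
  write_tsv_exact(dplyr::bind_rows(lapply(bs, `[[`, "variants")),
                  file.path(dir, "variants.tsv"))
  write_tsv_exact(dplyr::bind_rows(lapply(bs, `[[`, "segments")),
                  file.path(dir, "segments.tsv"))
  samples <- dplyr::bind_rows(lapply(bs, function(b) {
    dplyr::mutate(b$samples, patient_id = b$patient_id, .before = 1)
  }))
  write_tsv_exact(samples, file.path(dir, "samples.tsv"))
  clin <- cohort_clinical(cohort)
  if (nrow(clin)) {
    clin <- dplyr::mutate(clin, dplyr::across(
      dplyr::where(is.double),
      function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))))
    readr::write_csv(clin, file.path(dir, "clinical.csv"), na = ".")
  }
  write_tsv_exact(dplyr::bind_rows(lapply(bs, `[[`, "neoantigens")),
                  file.path(dir, "neoantigens.tsv"))
  hg <- dplyr::bind_rows(lapply(bs, function(b) {
    if (!length(b$hla_genotype)) return(NULL)
    tibble::tibble(patient_id = b$patient_id, allele = b$hla_genotype)
  }))
  write_tsv_exact(hg, file.path(dir, "hla_genotypes.tsv"))
  hc <- dplyr::bind_rows(lapply(bs, function(b) {
    if (!nrow(b$hla_allele_cn)) return(NULL)
    dplyr::mutate(b$hla_allele_cn, patient_id = b$patient_id, .before = 1)
  }))
  write_tsv_exact(hc, file.path(dir, "hla_allele_cn.tsv"))
  cdir <- file.path(dir, "clonotypes")
  dir.create(cdir, showWarnings = FALSE)
  for (b in bs) for (tab in b$repertoires) {
    path <- file.path(cdir, clonotype_file_name(tab))
    hdr <- sprintf("#total_templates=%s\n#input_cells=%s\n",
                   format(tab$total_templates, scientific = FALSE),
                   ifelse(is.na(tab$input_cells), ".",
                          format(tab$input_cells, scientific = FALSE)))
    con <- file(path, "wb")
    writeLines(sub("\n$", "", hdr), con, sep = "\n")
    close(con)
    write_tsv_exact(
      dplyr::mutate(tab$clones,
                    patient_id = tab$patient_id,
                    region_id = tab$region_id, .before = 1),
      path, append = TRUE, col_names = TRUE)
  }
  invisible(dir)
}

# ---- loading ---------------------------------------------------------------

# Doubles are parsed as text and converted with as.numeric (correctly
# rounded strtod) so that write/load round-trips are bit-exact.
read_tsv_strict <- function(path, cols, col_types = NULL,
                            double_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                       progress = FALSE, col_types = col_types)
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (dc in intersect(double_cols, names(x))) {
    x[[dc]] <- as.numeric(x[[dc]])
  }
  x[cols]
}

check_variant_rows <- function(v, path) {
  # row-level invariants; line numbers count the header as line 1
  bad <- function(cond, msg) {
    i <- which(cond)
    if (length(i)) {
      stop(sprintf("%s: line %d: %s", path, i[1] + 1L, msg), call. = FALSE)
    }
  }
  bad(is.na(v$pos) | v$pos < 1, "pos must be >= 1")
  bad(!is.na(v$t_vaf) & (v$t_vaf < 0 | v$t_vaf > 1), "t_vaf outside [0, 1]")
  bad(!is.na(v$t_alt) & !is.na(v$t_depth) & v$t_alt > v$t_depth,
      "t_alt exceeds t_depth")
  dup <- duplicated(variant_key(v))
  if (any(dup)) {
    stop(sprintf("%s: duplicate variant key: %s", path,
                 variant_key(v)[which(dup)[1]]), call. = FALSE)
  }
  invisible(v)
}

read_clonotype_file <- function(path) {
  hdr <- readLines(path, n = 2L)
  parse_hdr <- function(key) {
    ln <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (!length(ln)) stop(path, ": missing header line #", key, call. = FALSE)
    val <- sub(paste0("^#", key, "="), "", ln[1])
    if (val == ".") NA_real_ else as.numeric(val)
  }
  tot <- parse_hdr("total_templates")
  cells <- parse_hdr("input_cells")
  x <- readr::read_tsv(path, na = ".", comment = "#", show_col_types = FALSE,
                       progress = FALSE,
                       col_types = readr::cols(templates = "i",
                                               .default = "c"))
  x$productive_freq <- as.numeric(x$productive_freq)
  need <- c("patient_id", "region_id", "rearrangement", "templates",
            "productive_freq")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  clonotype_table(x$patient_id[1], x$region_id[1],
                  x[c("rearrangement", "templates", "productive_freq")],
                  total_templates = tot, input_cells = cells)
}

#' Load a cohort from delimited files
#'
#' Reads the MAF-like variant TSV, SEG-like segment TSV (with `a_count`,
#' `b_count` allele columns), per-sample clonotype TSVs, the clinical CSV and
#' the optional neoantigen/HLA tables, validating row-level invariants as it
#' goes (violations raise errors naming file and line). Missing optional
#' tables yield empty collections. Coordinates are 1-based inclusive.
#'
#' @param variant_path Variant TSV path.
#' @param segment_path Segment TSV path.
#' @param clonotype_dir Directory of clonotype TSVs (optional).
#' @param clinical_path Clinical CSV path (optional).
#' @param sample_path Per-region purity/ploidy TSV (optional).
#' @param neoantigen_path,hla_genotype_path,hla_cn_path Optional TSV paths.
#' @param config Named list stored on the cohort for provenance.
#' @return An `ith_cohort`.
#' @export
load_cohort <- function(variant_path, segment_path, clonotype_dir = NULL,
                        clinical_path = NULL, sample_path = NULL,
                        neoantigen_path = NULL, hla_genotype_path = NULL,
                        hla_cn_path = NULL, config = list()) {
  variants <- check_variant_rows(
    read_tsv_strict(variant_path, VARIANT_COLS,
                    readr::cols(pos = "i", t_depth = "i",
                                n_depth = "i", t_alt = "i",
                                .default = "c"),
                    double_cols = c("t_vaf", "n_vaf", "lod", "cadd",
                                    "popfreq_esp", "popfreq_1kg",
                                    "popfreq_exac")),
    variant_path)
  segments <- read_tsv_strict(
    segment_path, SEGMENT_COLS,
    readr::cols(a_count = "i", b_count = "i", .default = "c"),
    double_cols = c("start", "end", "log2"))
  if (any(segments$start > segments$end, na.rm = TRUE)) {
    i <- which(segments$start > segments$end)[1]
    stop(sprintf("%s: line %d: start > end", segment_path, i + 1L),
         call. = FALSE)
  }
  clinical <- NULL
  if (!is.null(clinical_path)) {
    clinical <- readr::read_csv(
      clinical_path, na = ".", show_col_types = FALSE, progress = FALSE,
      col_types = readr::cols(.default = "c"))
    missing <- setdiff(CLINICAL_COLS, names(clinical))
    if (length(missing)) {
      stop(sprintf("%s: missing column(s): %s", clinical_path,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    for (ic in c("os_event", "age")) {
      clinical[[ic]] <- as.integer(clinical[[ic]])
    }
    for (dc in c("os_months", "tumor_size_cm")) {
      clinical[[dc]] <- as.numeric(clinical[[dc]])
    }
  }
  samples <- NULL
  if (!is.null(sample_path)) {
    samples <- read_tsv_strict(
      sample_path, c("patient_id", "region_id", "purity", "ploidy"),
      readr::cols(.default = "c"), double_cols = c("purity", "ploidy"))
  }
  neo <- if (is.null(neoantigen_path) || !file.size(neoantigen_path)) {
    empty_neoantigens()
  } else read_tsv_strict(
    neoantigen_path, NEOANTIGEN_COLS,
    readr::cols(pos = "i", .default = "c"), double_cols = "ic50_nM")
  hg <- if (is.null(hla_genotype_path) || !file.size(hla_genotype_path)) {
    NULL
  } else read_tsv_strict(hla_genotype_path, c("patient_id", "allele"),
                         readr::cols(.default = "c"))
  hc <- if (is.null(hla_cn_path) || !file.size(hla_cn_path)) {
    NULL
  } else read_tsv_strict(hla_cn_path,
                         c("patient_id", "region_id", "allele", "bin", "cn"),
                         readr::cols(bin = "i", .default = "c"),
                         double_cols = "cn")
  reps <- list()
  if (!is.null(clonotype_dir) && dir.exists(clonotype_dir)) {
    files <- sort(list.files(clonotype_dir, pattern = "\\.tsv$",
                             full.names = TRUE))
    reps <- lapply(files, read_clonotype_file)
  }

  patients <- sort(unique(c(variants$patient_id, segments$patient_id,
                            clinical$patient_id, samples$patient_id)))
  bundles <- lapply(patients, function(p) {
    pv <- variants[variants$patient_id == p, ]
    ps <- segments[segments$patient_id == p, ]
    psam <- if (is.null(samples)) NULL else {
      samples[samples$patient_id == p, c("region_id", "purity", "ploidy")]
    }
    regions <- sort(unique(c(pv$region_id, ps$region_id, psam$region_id)))
    preps <- Filter(function(tb) tb$patient_id == p, reps)
    tumor_bundle(
      patient_id = p, regions = regions, variants = pv, segments = ps,
      samples = psam,
      hla_genotype = if (is.null(hg)) character() else hg$allele[hg$patient_id == p],
      hla_allele_cn = if (is.null(hc)) empty_hla_cn() else {
        hc[hc$patient_id == p, c("region_id", "allele", "bin", "cn")]
      },
      neoantigens = neo[neo$patient_id == p, ],
      clinical = if (is.null(clinical)) NULL else {
        clinical[clinical$patient_id == p, ]
      },
      repertoires = preps)
  })
  ith_cohort(bundles, config = config)
}

#' Load a cohort from a directory written by [write_cohort()]
#' @param dir Directory containing the cohort dialect files.
#' @param config Named list stored on the cohort.
#' @return An `ith_cohort`.
#' @export
load_cohort_dir <- function(dir, config = list()) {
  p <- function(f) {
    fp <- file.path(dir, f)
    if (file.exists(fp)) fp else NULL
  }
  load_cohort(file.path(dir, "variants.tsv"), file.path(dir, "segments.tsv"),
              clonotype_dir = file.path(dir, "clonotypes"),
              clinical_path = p("clinical.csv"), sample_path = p("samples.tsv"),
              neoantigen_path = p("neoantigens.tsv"),
              hla_genotype_path = p("hla_genotypes.tsv"),
              hla_cn_path = p("hla_allele_cn.tsv"), config = config)
}

# ---- validation ------------------------------------------------------------

violation <- function(patient, table, rule, detail) {
  tibble::tibble(patient = patient, table = table, rule = rule,
                 detail = detail)
}

#' Validate a cohort against the data-model invariants
#'
#' Checks every type invariant of the data model (coordinate sanity, VAF and
#' read-count consistency, unique variant keys, non-overlapping segments,
#' allele-count ordering, productive-frequency mass, neoantigen/variant locus
#' concordance, region references) and reports violations as data rather than
#' raising errors.
#'
#' @param cohort An `ith_cohort`.
#' @return Tibble with columns `patient`, `table`, `rule`, `detail`; zero rows
#'   iff the cohort is clean.
#' @export
validate_cohort <- function(cohort) {
  out <- list()
  for (b in cohort$bundles) {
    v <- b$variants
    if (nrow(v)) {
      if (any(v$pos < 1, na.rm = TRUE)) {
        out[[length(out) + 1]] <- violation(b$patient_id, "variants",
                                            "pos_ge_1", "pos < 1")
      }
      if (any(v$t_vaf < 0 | v$t_vaf > 1, na.rm = TRUE)) {
        out[[length(out) + 1]] <- violation(b$patient_id, "variants",
                                            "vaf_range", "t_vaf outside [0,1]")
      }
      if (any(v$t_alt > v$t_depth, na.rm = TRUE)) {
        out[[length(out) + 1]] <- violation(b$patient_id, "variants",
                                            "alt_le_depth", "t_alt > t_depth")
      }
      dup <- variant_key(v)[duplicated(variant_key(v))]
      if (length(dup)) {
        out[[length(out) + 1]] <- violation(b$patient_id, "variants",
                                            "unique_key",
                                            paste(unique(dup), collapse = "; "))
      }
      extra <- setdiff(unique(v$region_id), b$regions)
      if (length(extra)) {
        out[[length(out) + 1]] <- violation(b$patient_id, "variants",
                                            "region_known",
                                            paste(extra, collapse = "; "))
      }
    }
    s <- b$segments
    if (nrow(s)) {
      if (any(s$start > s$end, na.rm = TRUE)) {
        out[[length(out) + 1]] <- violation(b$patient_id, "segments",
                                            "start_le_end", "start > end")
      }
      if (any(s$b_count > s$a_count | s$b_count < 0, na.rm = TRUE)) {
        out[[length(out) + 1]] <- violation(b$patient_id, "segments",
                                            "allele_order",
                                            "requires a_count >= b_count >= 0")
      }
      ov <- s |>
        dplyr::group_by(.data$region_id, .data$chrom) |>
        dplyr::arrange(.data$start, .by_group = TRUE) |>
        dplyr::filter(dplyr::lag(.data$end, default = -Inf) >= .data$start) |>
        dplyr::ungroup()
      if (nrow(ov)) {
        # name both members of the first overlapping pair
        r <- ov[1, ]
        prev <- s[s$region_id == r$region_id & s$chrom == r$chrom &
                    s$start < r$start & s$end >= r$start, ][1, ]
        out[[length(out) + 1]] <- violation(
          b$patient_id, "segments", "no_overlap",
          sprintf("%s:%s-%s overlaps %s:%s-%s in region %s",
                  r$chrom, r$start, r$end, prev$chrom, prev$start, prev$end,
                  r$region_id))
      }
    }
    for (tab in b$repertoires) {
      tbl_name <- sprintf("clonotypes[%s]", tab$region_id)
      pf <- sum(tab$clones$productive_freq)
      if (pf > 1 + 1e-6) {
        out[[length(out) + 1]] <- violation(
          b$patient_id, tbl_name, "freq_mass",
          sprintf("productive_freq sums to %.4f", pf))
      }
      if (any(tab$clones$templates < 1)) {
        out[[length(out) + 1]] <- violation(b$patient_id, tbl_name,
                                            "templates_ge_1", "templates < 1")
      }
      if (anyDuplicated(tab$clones$rearrangement)) {
        out[[length(out) + 1]] <- violation(b$patient_id, tbl_name,
                                            "unique_rearrangement",
                                            "duplicate rearrangement")
      }
    }
    if (nrow(b$neoantigens)) {
      nk <- mutation_key(b$neoantigens)
      vk <- mutation_key(b$variants)
      orphan <- setdiff(nk, vk)
      if (length(orphan)) {
        out[[length(out) + 1]] <- violation(
          b$patient_id, "neoantigens", "locus_in_variants",
          paste(orphan, collapse = "; "))
      }
    }
  }
  if (!length(out)) {
    violation(character(), character(), character(), character())
  } else {
    dplyr::bind_rows(out)
  }
}

# ---- result serialization --------------------------------------------------

#' Write named result tables with a manifest
#'
#' Writes one TSV per table plus `manifest.tsv` listing file names, row
#' counts, MD5 checksums and a configuration hash. Output is byte-identical
#' across runs on identical inputs, which makes full-pipeline determinism
#' checkable from the manifest alone.
#'
#' @param results Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param config Optional named list hashed into the manifest.
#' @return The manifest tibble, invisibly.
#' @export
write_results <- function(results, out_dir, config = list()) {
  if (is.null(names(results)) || any(names(results) == "") ||
      anyDuplicated(names(results))) {
    stop("results must be uniquely named (name collision or missing name)",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- paste0(names(results), ".tsv")
  rows <- integer(length(results))
  for (i in seq_along(results)) {
    write_tsv_exact(tibble::as_tibble(results[[i]]),
                    file.path(out_dir, files[i]))
    rows[i] <- nrow(results[[i]])
  }
  md5 <- unname(tools::md5sum(file.path(out_dir, files)))
  manifest <- tibble::tibble(file = files, n_rows = rows, md5 = md5,
                             config_hash = rlang::hash(config))
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}
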