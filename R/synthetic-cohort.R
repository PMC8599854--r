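# Synthetic multi-region cohort generator with known ground truth.
#
# The generator emulates the data structures of a limited-stage SCLC
# multi-region study: FFPE exomes at ~180x with a log-odds QC score, a
# mostly-truncal mutation architecture, high CNA burden with frequent LOH,
# HLA allele-specific copy estimates, predicted neoantigens, immunoSEQ-style
# TCR-beta repertoires, and exponential proportional-hazards survival.
# Every observable is derived from an explicit GroundTruth plus documented
# noise; with noise off the pipeline recovers the truth exactly.

#' Simulation configuration
#'
#' Defaults are the study conditions: 19 patients (13 with three regions, 5
#' with two, 1 single-region), ~200 mutations per tumor of which 80% are
#' truncal, tumor depth negative-binomial around 180x, purity 0.5-0.9,
#' smoking-signature-dominant trunk mutations versus a
#' DSB-repair-signature-heavy nontrunk compartment, HLA LOH in about half
#' the tumors, and sparse, heterogeneous TCR repertoires.
#'
#' @param n_patients Number of patients.
#' @param region_counts Integer vector of regions per tumor (recycled);
#'   default mirrors the study pattern (3,3,...,2,...,1).
#' @param mutations_per_tumor Somatic mutations per tumor.
#' @param trunk_fraction Fraction of mutations present in all regions.
#' @param purity_range Tumor-purity interval.
#' @param clonal_ccf CCF of truncal/clonal mutations (1.0).
#' @param subclonal_ccf_range CCF interval for subclonal mutations.
#' @param trunk_signature_mix,branch_signature_mix Named weight vectors over
#'   the 30 reference signatures (must each sum to 1).
#' @param mean_depth,depth_dispersion Tumor-depth negative-binomial mean and
#'   size.
#' @param normal_depth Mean germline depth.
#' @param segments_per_region Approximate copy-number segments per region.
#' @param p_gene_gain,p_gene_loss Per-gene probabilities of a gain/loss
#'   event per tumor.
#' @param p_cnn_loh Per-gene probability of a copy-neutral LOH event.
#' @param loh_neoantigen_bias Multiplier on `p_cnn_loh` for neoantigen-
#'   associated genes (1 = unbiased).
#' @param p_ifng_loss Per-gene loss probability for IFN-gamma pathway genes.
#' @param burden_dispersion Log-normal sdlog of the per-tumor multiplier on
#'   all copy-number event probabilities; reproduces the strong
#'   between-patient variation in CNA burden and couples IFN-gamma loss to
#'   the overall burden.
#' @param p_hla_loh Probability a tumor carries HLA LOH.
#' @param trunk_cna_fraction Probability a planted CNA/LOH event is truncal.
#' @param hla_bins Copy-estimate bins per HLA allele per region.
#' @param clone_size_alpha Zipf exponent of clone frequencies; larger values
#'   concentrate mass on the top clones (higher clonality).
#' @param shared_clone_fraction Fraction of each region's clonotypes drawn
#'   from the tumor-wide shared pool.
#' @param repertoire_size Clonotypes per tumor-region repertoire.
#' @param total_templates,input_cells Sequenced templates and nucleated-cell
#'   input per tumor repertoire.
#' @param neoantigen_rate Fraction of nonsynonymous mutations yielding a
#'   candidate peptide.
#' @param p_low_lod Fraction of multi-region calls given a sub-threshold LOD
#'   in one region (exercises the rescue rule).
#' @param ffpe_artifact_rate Artifact calls per true mutation per region
#'   (low-LOD, low-VAF, C>T-heavy).
#' @param survival_betas Named log-hazard coefficients on standardized
#'   covariates (`tmb`, `cna_burden`).
#' @param censoring_rate Expected fraction censored.
#' @param capture_mb Exome footprint for the TMB covariate.
#' @param noise If `FALSE`, depths are fixed, counts are expectations, and
#'   no artifacts or low-LOD calls are injected (exact ground-truth mode).
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 19,
                              region_counts = NULL,
                              mutations_per_tumor = 200,
                              trunk_fraction = 0.8,
                              purity_range = c(0.5, 0.9),
                              clonal_ccf = 1.0,
                              subclonal_ccf_range = c(0.2, 0.6),
                              trunk_signature_mix = default_trunk_mix(),
                              branch_signature_mix = default_branch_mix(),
                              mean_depth = 180,
                              depth_dispersion = 25,
                              normal_depth = 161,
                              segments_per_region = 60,
                              p_gene_gain = 0.05,
                              p_gene_loss = 0.05,
                              p_cnn_loh = 0.05,
                              loh_neoantigen_bias = 1,
                              p_ifng_loss = 0.2,
                              burden_dispersion = 0.6,
                              p_hla_loh = 9 / 19,
                              trunk_cna_fraction = 0.85,
                              hla_bins = 10,
                              clone_size_alpha = 0.45,
                              shared_clone_fraction = 0.12,
                              repertoire_size = 500,
                              total_templates = 1000,
                              input_cells = 60000,
                              neoantigen_rate = 0.3,
                              p_low_lod = 0.1,
                              ffpe_artifact_rate = 0.15,
                              survival_betas = c(tmb = -0.3,
                                                 cna_burden = 0.3),
                              censoring_rate = 0.3,
                              capture_mb = 30,
                              noise = TRUE,
                              seed = 1) {
  if (is.null(region_counts)) {
    pattern <- c(rep(3, 13), rep(2, 5), 1)
    region_counts <- if (n_patients == 19) pattern else {
      rep_len(c(3, 3, 2), n_patients)
    }
  }
  region_counts <- rep_len(region_counts, n_patients)
  cfg <- as.list(environment())
  cfg$pattern <- NULL
  fracs <- c(trunk_fraction, p_gene_gain, p_gene_loss, p_cnn_loh,
             p_ifng_loss, p_hla_loh, trunk_cna_fraction,
             shared_clone_fraction, neoantigen_rate, p_low_lod)
  stopifnot(all(fracs >= 0 & fracs <= 1),
            abs(sum(trunk_signature_mix) - 1) < 1e-9,
            abs(sum(branch_signature_mix) - 1) < 1e-9,
            clone_size_alpha > 0, censoring_rate >= 0,
            purity_range[1] > 0, purity_range[2] <= 1)
  if (trunk_fraction < 1 && all(region_counts == 1)) {
    stop("infeasible config: non-trunk mutations require > 1 region",
         call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_trunk_mix <- function() {
  w <- setNames(numeric(30), paste0("Signature.", 1:30))
  w[c("Signature.4", "Signature.1", "Signature.5", "Signature.3",
      "Signature.13")] <- c(0.62, 0.15, 0.10, 0.06, 0.07)
  w
}

#' @rdname simulation_config
#' @export
default_branch_mix <- function() {
  w <- setNames(numeric(30), paste0("Signature.", 1:30))
  w[c("Signature.3", "Signature.4", "Signature.1", "Signature.5",
      "Signature.13")] <- c(0.45, 0.29, 0.10, 0.10, 0.06)
  w
}

channel_to_alleles <- function(channel, flip) {
  # channel "A[C>A]T" -> tnc string + ref/alt alleles, optionally presented
  # on the purine strand to exercise downstream collapsing
  up <- substr(channel, 1, 1); ref <- substr(channel, 3, 3)
  alt <- substr(channel, 5, 5); dn <- substr(channel, 7, 7)
  ref3 <- c(up, ref, dn); alt3 <- c(up, alt, dn)
  if (flip) {
    ref3 <- rev(unname(COMPLEMENT[ref3]))
    alt3 <- rev(unname(COMPLEMENT[alt3]))
  }
  list(tnc = paste0(paste(ref3, collapse = ""), ">",
                    paste(alt3, collapse = "")),
       ref = ref3[2], alt = alt3[2])
}

draw_channels <- function(n, mix, reference) {
  probs <- as.vector(reference %*% mix)
  sample(rownames(reference), n, replace = TRUE, prob = probs)
}

rand_dna <- function(n, len = 30) {
  vapply(seq_len(n), function(i) {
    paste(sample(BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

HLA_POOL <- list(A = c("A*01:01", "A*02:01", "A*03:01", "A*11:01", "A*24:02"),
                 B = c("B*07:02", "B*08:01", "B*15:01", "B*35:01", "B*44:02"),
                 C = c("C*01:02", "C*03:04", "C*04:01", "C*07:01", "C*07:02"))

#' Simulate a full multi-region cohort with ground truth
#'
#' Generates variants (binomial read-count model on purity- and CCF-scaled
#' expected VAFs), allele-specific copy-number segments with planted gain/
#' loss/LOH events, HLA genotypes with binned allele copy estimates and
#' planted HLA LOH, predicted neoantigens, TCR-beta repertoires, and
#' proportional-hazards survival, all tied to an explicit ground truth.
#' Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List with `cohort` (an `ith_cohort`) and `truth` (list of
#'   ground-truth tibbles: `mutations`, `tumors`, `cna_events`, `hla_loh`,
#'   `shared_clones`, `survival`).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ref <- reference_signatures()
  genes <- default_gene_model()
  ifng <- default_ifng_genes()

  bundles <- list()
  truth_mut <- list(); truth_tumor <- list(); truth_cna <- list()
  truth_hla <- list(); truth_shared <- list()

  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", i)
    k <- config$region_counts[i]
    regions <- sprintf("R%d", seq_len(k))
    purity <- if (config$noise) {
      runif(k, config$purity_range[1], config$purity_range[2])
    } else rep(mean(config$purity_range), k)
    names(purity) <- regions

    # ---- mutations --------------------------------------------------------
    n_mut <- config$mutations_per_tumor
    compartment <- if (k == 1) {
      rep("trunk", n_mut)
    } else {
      draw <- runif(n_mut)
      nontrunk_type <- if (k >= 3) {
        ifelse(runif(n_mut) < 0.5, "branch", "private")
      } else "private"
      ifelse(draw < config$trunk_fraction, "trunk", nontrunk_type)
    }
    gene_idx <- sample(nrow(genes), n_mut, replace = TRUE)
    pos <- genes$start[gene_idx] +
      sample.int(19000, n_mut, replace = TRUE)
    func_class <- sample(c("nonsynonymous", "synonymous", "stopgain",
                           "frameshift", "other"),
                         n_mut, replace = TRUE,
                         prob = c(0.68, 0.12, 0.08, 0.07, 0.05))
    ccf <- ifelse(compartment == "trunk", config$clonal_ccf,
                  if (config$noise) {
                    runif(n_mut, config$subclonal_ccf_range[1],
                          config$subclonal_ccf_range[2])
                  } else mean(config$subclonal_ccf_range))
    branch_sizes <- 2:max(k - 1, 2)   # guard sample()'s scalar expansion
    region_sets <- lapply(seq_len(n_mut), function(j) {
      switch(compartment[j],
             trunk = regions,
             branch = sort(sample(regions,
                                  branch_sizes[sample.int(
                                    length(branch_sizes), 1)])),
             private = sample(regions, 1))
    })
    channels <- character(n_mut)
    trunk_sel <- compartment == "trunk"
    channels[trunk_sel] <- draw_channels(sum(trunk_sel),
                                         config$trunk_signature_mix, ref)
    channels[!trunk_sel] <- draw_channels(sum(!trunk_sel),
                                          config$branch_signature_mix, ref)
    flip <- if (config$noise) runif(n_mut) < 0.5 else rep(FALSE, n_mut)
    alle <- lapply(seq_len(n_mut), function(j) {
      channel_to_alleles(channels[j], flip[j])
    })
    is_indel <- func_class == "frameshift"
    ref_allele <- vapply(alle, `[[`, "", "ref")
    alt_allele <- vapply(alle, `[[`, "", "alt")
    tnc <- vapply(alle, `[[`, "", "tnc")
    ref_allele[is_indel] <- paste0(ref_allele[is_indel], "A")
    tnc[is_indel] <- NA_character_
    cadd <- ifelse(func_class == "nonsynonymous",
                   ifelse(runif(n_mut) < 0.2, runif(n_mut, 21, 40),
                          runif(n_mut, 0, 20)),
                   NA_real_)

    mut_tbl <- tibble::tibble(
      patient_id = pid,
      chrom = genes$chrom[gene_idx], pos = as.integer(pos),
      ref = ref_allele, alt = alt_allele, gene = genes$gene[gene_idx],
      func_class = func_class, tnc = tnc, cadd = cadd,
      compartment = compartment, ccf = ccf,
      regions_present = vapply(region_sets, paste, "", collapse = ","))
    # drop accidental duplicate loci so variant keys stay unique
    dup <- duplicated(paste(mut_tbl$chrom, mut_tbl$pos, mut_tbl$ref,
                            mut_tbl$alt))
    mut_tbl <- mut_tbl[!dup, ]
    region_sets <- region_sets[!dup]
    n_mut <- nrow(mut_tbl)

    n_present <- lengths(region_sets)
    idx <- rep(seq_len(n_mut), n_present)
    reg_vec <- unlist(region_sets)
    n_rows <- length(idx)
    # one low-LOD region per selected multi-region mutation, never the first
    # listed region, so the rescue rule always has a passing supporter
    low_lod <- rep(FALSE, n_rows)
    first_of <- !duplicated(idx)
    if (config$noise) {
      sel_mut <- which(n_present >= 2 & runif(n_mut) < config$p_low_lod)
      for (j in sel_mut) {
        cand <- which(idx == j & !first_of)
        low_lod[cand[sample.int(length(cand), 1)]] <- TRUE
      }
    }
    depth <- if (config$noise) {
      pmax(30L, rnbinom(n_rows, mu = config$mean_depth,
                        size = config$depth_dispersion))
    } else rep(as.integer(config$mean_depth), n_rows)
    evaf <- unname(purity[reg_vec]) * mut_tbl$ccf[idx] / 2
    alt_n <- if (config$noise) rbinom(n_rows, depth, evaf) else {
      as.integer(round(depth * evaf))
    }
    alt_n <- pmax(alt_n, 1L)  # detected calls have >= 1 alt read
    variants <- tibble::tibble(
      patient_id = pid, region_id = reg_vec, chrom = mut_tbl$chrom[idx],
      pos = mut_tbl$pos[idx], ref = mut_tbl$ref[idx],
      alt = mut_tbl$alt[idx], gene = mut_tbl$gene[idx],
      func_class = mut_tbl$func_class[idx],
      t_depth = as.integer(depth),
      n_depth = if (config$noise) {
        pmax(20L, rnbinom(n_rows, mu = config$normal_depth, size = 25))
      } else rep(as.integer(config$normal_depth), n_rows),
      t_alt = as.integer(alt_n), t_vaf = alt_n / depth, n_vaf = 0,
      lod = ifelse(low_lod, runif(n_rows, 5, 18), runif(n_rows, 35, 120)),
      cadd = mut_tbl$cadd[idx],
      popfreq_esp = 0, popfreq_1kg = 0, popfreq_exac = 0,
      tnc = mut_tbl$tnc[idx])

    # FFPE artifacts: non-recurrent low-LOD low-VAF C>T-heavy calls
    if (config$noise && config$ffpe_artifact_rate > 0) {
      n_art <- stats::rpois(1, config$ffpe_artifact_rate * n_mut * k)
      if (n_art > 0) {
        ct_channels <- grep("\\[C>T\\]", rownames(ref), value = TRUE)
        art_ch <- sample(ct_channels, n_art, replace = TRUE)
        art_alle <- lapply(art_ch, channel_to_alleles, flip = FALSE)
        art_gene <- sample(nrow(genes), n_art, replace = TRUE)
        art <- tibble::tibble(
          patient_id = pid,
          region_id = sample(regions, n_art, replace = TRUE),
          chrom = genes$chrom[art_gene],
          pos = as.integer(genes$start[art_gene] + 19000 +
                             sample.int(900, n_art, replace = TRUE)),
          ref = vapply(art_alle, `[[`, "", "ref"),
          alt = vapply(art_alle, `[[`, "", "alt"),
          gene = genes$gene[art_gene], func_class = "nonsynonymous",
          t_depth = pmax(30L, rnbinom(n_art, mu = config$mean_depth,
                                      size = config$depth_dispersion)),
          n_depth = as.integer(config$normal_depth),
          n_vaf = 0, lod = runif(n_art, 2, 14),
          cadd = NA_real_, popfreq_esp = 0, popfreq_1kg = 0,
          popfreq_exac = 0,
          tnc = vapply(art_alle, `[[`, "", "tnc")) |>
          dplyr::mutate(
            t_alt = pmax(2L, rbinom(n_art, .data$t_depth,
                                    runif(n_art, 0.02, 0.08))),
            t_vaf = .data$t_alt / .data$t_depth)
        art <- art[!duplicated(paste(art$region_id, art$chrom, art$pos,
                                     art$ref, art$alt)), ]
        keys <- paste(variants$chrom, variants$pos, variants$ref,
                      variants$alt)
        art <- art[!(paste(art$chrom, art$pos, art$ref, art$alt) %in% keys), ]
        variants <- dplyr::bind_rows(variants, art[names(variants)])
      }
    }

    # ---- copy number ------------------------------------------------------
    neo_genes_pool <- unique(mut_tbl$gene[mut_tbl$func_class ==
                                            "nonsynonymous"])
    # tumor-wide event-rate multiplier: CNA burden varies strongly between
    # patients, and IFN-gamma losses ride the same instability
    bmult <- if (config$noise) {
      rlnorm(1, 0, config$burden_dispersion)
    } else 1
    p_gain <- min(1, config$p_gene_gain * bmult)
    p_loss <- min(1, config$p_gene_loss * bmult)
    gene_state <- rep("neutral", nrow(genes))
    loh_state <- rep("none", nrow(genes))
    u <- runif(nrow(genes))
    gene_state[u < p_gain] <- "gain"
    gene_state[u >= p_gain & u < p_gain + p_loss] <- "loss"
    ifng_sel <- genes$gene %in% ifng &
      runif(nrow(genes)) < min(1, config$p_ifng_loss * bmult)
    gene_state[ifng_sel] <- "loss"
    p_loh <- ifelse(genes$gene %in% neo_genes_pool,
                    pmin(1, config$p_cnn_loh * config$loh_neoantigen_bias *
                           bmult),
                    min(1, config$p_cnn_loh * bmult))
    cnn_sel <- gene_state == "neutral" & runif(nrow(genes)) < p_loh
    loh_state[cnn_sel] <- "CNN_LOH"
    loh_state[gene_state == "loss"] <- "CNL_LOH"

    event_idx <- which(gene_state != "neutral" | loh_state == "CNN_LOH")
    event_scope <- ifelse(runif(length(event_idx)) <
                            config$trunk_cna_fraction, "trunk", "branch")
    if (k == 1) event_scope[] <- "trunk"
    sub_sizes <- seq_len(max(k - 1, 1))
    event_regions <- lapply(seq_along(event_idx), function(e) {
      if (event_scope[e] == "trunk") regions else {
        sort(sample(regions, sub_sizes[sample.int(length(sub_sizes), 1)]))
      }
    })
    cna_truth <- tibble::tibble(
      patient_id = pid, gene = genes$gene[event_idx],
      state = gene_state[event_idx], loh_class = loh_state[event_idx],
      scope = event_scope,
      regions = vapply(event_regions, paste, "", collapse = ","))

    seg_rows <- list()
    for (r in regions) {
      st <- rep("neutral", nrow(genes))
      lo <- rep("none", nrow(genes))
      for (e in seq_along(event_idx)) {
        if (r %in% event_regions[[e]]) {
          st[event_idx[e]] <- gene_state[event_idx[e]]
          lo[event_idx[e]] <- loh_state[event_idx[e]]
        }
      }
      key <- paste(st, lo)
      for (ch in unique(genes$chrom)) {
        sel <- which(genes$chrom == ch)
        runs <- rle(key[sel])
        ends_idx <- cumsum(runs$lengths)
        starts_idx <- c(1, utils::head(ends_idx, -1) + 1)
        for (q in seq_along(runs$lengths)) {
          gi <- sel[starts_idx[q]:ends_idx[q]]
          s_state <- st[gi[1]]; s_loh <- lo[gi[1]]
          start <- if (starts_idx[q] == 1) 1 else {
            floor((genes$end[sel[starts_idx[q] - 1]] +
                     genes$start[gi[1]]) / 2) + 1
          }
          end <- if (ends_idx[q] == length(sel)) {
            genes$end[sel[length(sel)]] + 5e5
          } else {
            floor((genes$end[gi[length(gi)]] +
                     genes$start[sel[ends_idx[q] + 1]]) / 2)
          }
          base_log2 <- switch(s_state, gain = 0.9, loss = -0.9, 0)
          jitter <- if (config$noise) rnorm(1, 0, 0.04) else 0
          ab <- if (s_state == "gain") c(2L, 1L)
            else if (s_state == "loss") c(1L, 0L)
            else if (s_loh == "CNN_LOH") c(2L, 0L)
            else c(1L, 1L)
          seg_rows[[length(seg_rows) + 1]] <- tibble::tibble(
            patient_id = pid, region_id = r, chrom = ch,
            start = start, end = end, log2 = base_log2 + jitter,
            a_count = ab[1], b_count = ab[2])
        }
      }
    }
    segments <- dplyr::bind_rows(seg_rows)
    ploidy <- segments |>
      dplyr::group_by(.data$region_id) |>
      dplyr::summarise(ploidy = sum((.data$a_count + .data$b_count) *
                                      (.data$end - .data$start + 1)) /
                         sum(.data$end - .data$start + 1)) |>
      tibble::deframe()

    # ---- neoantigens ------------------------------------------------------
    # class-I presentation is skewed (immunodominant alleles present most
    # binders), which is also what makes their loss worthwhile for the tumor
    hla_genotype <- unlist(lapply(HLA_POOL, function(pool) {
      sample(pool, 2)
    }), use.names = FALSE)
    presentation_probs <- c(8, 4, 2, 1, 0.5, 0.5)[order(order(runif(6)))]
    neo_sel <- which(mut_tbl$func_class == "nonsynonymous" &
                       runif(n_mut) < config$neoantigen_rate)
    neoantigens <- if (length(neo_sel)) {
      tibble::tibble(
        patient_id = pid,
        chrom = mut_tbl$chrom[neo_sel], pos = mut_tbl$pos[neo_sel],
        ref = mut_tbl$ref[neo_sel], alt = mut_tbl$alt[neo_sel],
        gene = mut_tbl$gene[neo_sel],
        peptide = vapply(seq_along(neo_sel), function(z) {
          paste(sample(LETTERS[1:20], 9, replace = TRUE), collapse = "")
        }, character(1)),
        allele = sample(hla_genotype, length(neo_sel), replace = TRUE,
                        prob = presentation_probs),
        ic50_nM = if (config$noise) {
          rlnorm(length(neo_sel), log(300), 1.1)
        } else rep(100, length(neo_sel)))
    } else empty_neoantigens()

    # ---- HLA --------------------------------------------------------------
    # immune pressure selects for losing the allele presenting the most
    # binders
    has_loh <- runif(1) < config$p_hla_loh && k >= 1
    lost_allele <- if (!has_loh) NA_character_ else {
      binders <- neoantigens[!is.na(neoantigens$ic50_nM) &
                               neoantigens$ic50_nM < 500, ]
      if (nrow(binders)) {
        names(which.max(table(factor(binders$allele,
                                     levels = hla_genotype))))
      } else sample(hla_genotype, 1)
    }
    loh_scope <- if (!has_loh) NA_character_ else {
      if (k == 1 || runif(1) < 5 / 9) "trunk" else "branch"
    }
    loh_regions <- if (!has_loh) character() else {
      if (loh_scope == "trunk") regions else {
        sz <- seq_len(max(k - 1, 1))
        sort(sample(regions, sz[sample.int(length(sz), 1)]))
      }
    }
    hla_cn <- tidyr::crossing(region_id = regions, allele = hla_genotype,
                              bin = seq_len(config$hla_bins)) |>
      dplyr::mutate(cn = 1)
    if (config$noise) hla_cn$cn <- rnorm(nrow(hla_cn), 1, 0.08)
    if (has_loh) {
      hom <- hla_genotype[sub("\\*.*", "", hla_genotype) ==
                            sub("\\*.*", "", lost_allele) &
                            hla_genotype != lost_allele]
      sel_lost <- hla_cn$region_id %in% loh_regions &
        hla_cn$allele == lost_allele
      sel_hom <- hla_cn$region_id %in% loh_regions & hla_cn$allele %in% hom
      hla_cn$cn[sel_lost] <- if (config$noise) {
        pmax(0, rnorm(sum(sel_lost), 0.15, 0.05))
      } else 0.15
      hla_cn$cn[sel_hom] <- if (config$noise) {
        rnorm(sum(sel_hom), 1.7, 0.1)
      } else 1.7
    }
    truth_hla[[pid]] <- tibble::tibble(
      patient_id = pid, has_loh = has_loh, lost_allele = lost_allele,
      scope = loh_scope,
      regions = paste(loh_regions, collapse = ","))

    # ---- repertoires ------------------------------------------------------
    n_shared <- round(config$shared_clone_fraction * config$repertoire_size)
    shared_pool <- rand_dna(n_shared)
    repertoires <- lapply(regions, function(r) {
      simulate_repertoire(config, list(
        patient_id = pid, region_id = r, shared_pool = shared_pool))
    })
    adj <- simulate_repertoire(config, list(
      patient_id = pid, region_id = adjacent_lung_region(),
      shared_pool = character(),
      size = 4L * config$repertoire_size,
      alpha = config$clone_size_alpha * 1.6,
      total_templates = 10L * config$total_templates,
      input_cells = config$input_cells))
    repertoires <- c(repertoires, list(adj))
    truth_shared[[pid]] <- tibble::tibble(patient_id = pid,
                                          rearrangement = shared_pool)

    truth_mut[[pid]] <- dplyr::mutate(
      mut_tbl, mutation = paste(.data$chrom, .data$pos, .data$ref,
                                .data$alt, sep = ":"))
    truth_cna[[pid]] <- cna_truth
    truth_tumor[[pid]] <- tibble::tibble(
      patient_id = pid, n_regions = k,
      trunk_fraction = mean(mut_tbl$compartment == "trunk"),
      n_mutations = n_mut)

    bundles[[pid]] <- tumor_bundle(
      patient_id = pid, regions = regions, variants = variants,
      segments = segments,
      samples = tibble::tibble(region_id = regions,
                               purity = unname(purity[regions]),
                               ploidy = unname(ploidy[regions])),
      hla_genotype = hla_genotype, hla_allele_cn = hla_cn,
      neoantigens = neoantigens, repertoires = repertoires)
  }

  truth <- list(mutations = dplyr::bind_rows(truth_mut),
                tumors = dplyr::bind_rows(truth_tumor),
                cna_events = dplyr::bind_rows(truth_cna),
                hla_loh = dplyr::bind_rows(truth_hla),
                shared_clones = dplyr::bind_rows(truth_shared),
                signature_mix = tibble::tibble(
                  compartment = rep(c("trunk", "nontrunk"), each = 30),
                  signature = rep(paste0("Signature.", 1:30), 2),
                  weight = c(unname(config$trunk_signature_mix),
                             unname(config$branch_signature_mix))))

  # ---- clinical / survival ----------------------------------------------
  cohort <- ith_cohort(bundles, config = unclass(config))
  covariates <- cohort_covariates(cohort, config$capture_mb)
  clin <- simulate_survival(covariates, config$survival_betas,
                            config$censoring_rate)
  for (pid in names(bundles)) {
    b <- cohort$bundles[[pid]]
    b$clinical <- clin[clin$patient_id == pid, ]
    cohort$bundles[[pid]] <- b
  }
  truth$survival <- list(betas = config$survival_betas,
                         covariates = covariates)
  list(cohort = cohort, truth = truth)
}

cohort_covariates <- function(cohort, capture_mb = 30) {
  vars <- cohort_variants(cohort)
  tmb <- compute_tmb(vars, capture_mb)
  tmb <- tmb[is.na(tmb$region_id), c("patient_id", "tmb")]
  calls <- gene_level_cna(dplyr::bind_rows(
    lapply(cohort$bundles, `[[`, "segments")))
  burden <- cna_burden(calls)$per_tumor
  dplyr::left_join(tmb, dplyr::rename(burden, cna_burden = "burden"),
                   by = "patient_id") |>
    dplyr::mutate(cna_burden = dplyr::coalesce(.data$cna_burden, 0L))
}

#' Simulate one TCR-beta repertoire
#'
#' Clone frequencies follow a Zipf law with exponent `clone_size_alpha`
#' (larger = more mass on the top clones); a `shared_clone_fraction` of the
#' region's clonotypes is drawn from the tumor-wide shared pool and the rest
#' are region-unique; template counts are multinomial at the configured
#' total. Uses the current RNG stream (seed it, or call within
#' [simulate_cohort()]).
#'
#' @param config A [simulation_config()].
#' @param context List with `patient_id`, `region_id`, `shared_pool`
#'   (character vector), and optional overrides `size`, `alpha`,
#'   `total_templates`, `input_cells`.
#' @return A [clonotype_table()].
#' @export
simulate_repertoire <- function(config, context) {
  size <- context$size %||% config$repertoire_size
  alpha <- context$alpha %||% config$clone_size_alpha
  total <- context$total_templates %||% config$total_templates
  cells <- context$input_cells %||% config$input_cells
  if (alpha <= 0) stop("clone_size_alpha must be > 0", call. = FALSE)
  stopifnot(size >= 1)
  n_shared <- min(length(context$shared_pool), size)
  shared <- if (n_shared) sample(context$shared_pool, n_shared) else
    character()
  unique_clones <- rand_dna(size - n_shared)
  clones <- sample(c(shared, unique_clones))  # shuffle rank assignment
  p <- seq_len(size)^(-alpha)
  p <- p / sum(p)
  templ <- as.vector(rmultinom(1, total, p))
  keep <- templ > 0
  tab <- tibble::tibble(rearrangement = clones[keep],
                        templates = templ[keep]) |>
    dplyr::mutate(productive_freq = .data$templates / sum(.data$templates)) |>
    dplyr::arrange(dplyr::desc(.data$templates), .data$rearrangement)
  clonotype_table(context$patient_id, context$region_id, tab,
                  total_templates = total, input_cells = cells)
}

#' Simulate survival records under a proportional-hazards model
#'
#' Event times are exponential with hazard `h0 * exp(beta . z)` where `z`
#' are the standardized covariates; censoring is independent exponential
#' calibrated so the expected censored fraction matches `censoring_rate`
#' (0 = none, >= 1 = everything censored). Also draws the demographic
#' clinical fields.
#'
#' @param covariates Tibble with `patient_id` and one column per named
#'   coefficient.
#' @param betas Named log-hazard coefficients (names must be covariate
#'   columns).
#' @param censoring_rate Expected censored fraction (>= 0).
#' @param seed Optional seed (omit to use the current RNG stream).
#' @param base_hazard Baseline hazard per month (default 1/40).
#' @return Clinical tibble (`patient_id`, `os_months`, `os_event`, `stage`,
#'   `age`, `sex`, `smoking`, `tumor_size_cm`).
#' @export
simulate_survival <- function(covariates, betas, censoring_rate = 0.3,
                              seed = NULL, base_hazard = 1 / 40) {
  if (censoring_rate < 0) stop("censoring_rate must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(covariates)
  miss <- setdiff(names(betas), names(covariates))
  if (length(miss)) stop("covariates missing: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  z <- scale(as.matrix(covariates[names(betas)]))
  z[is.nan(z)] <- 0
  lp <- as.vector(z %*% betas)
  t_event <- rexp(n, rate = base_hazard * exp(lp))
  if (censoring_rate >= 1) {
    time <- t_event; event <- rep(0L, n)
  } else if (censoring_rate == 0) {
    time <- t_event; event <- rep(1L, n)
  } else {
    c_rate <- base_hazard * censoring_rate / (1 - censoring_rate)
    t_cens <- rexp(n, rate = c_rate)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  }
  tibble::tibble(
    patient_id = covariates$patient_id,
    os_months = round(time, 2), os_event = event,
    stage = sample(c("I", "II", "III"), n, replace = TRUE,
                   prob = c(0.45, 0.34, 0.21)),
    age = sample(38:83, n, replace = TRUE),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.84, 0.16)),
    smoking = sample(c("smoker", "never"), n, replace = TRUE,
                     prob = c(0.76, 0.24)),
    tumor_size_cm = round(runif(n, 1, 10), 1))
}
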