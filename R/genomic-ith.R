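# Genomic intratumor heterogeneity: presence/absence matrices, trunk/branch/
# private classification, pairwise mutational Jaccard indices, exhaustive
# Wagner-parsimony trees rooted at an all-zero germline ancestor, cancer-cell
# fractions, and tumor-level clonal architecture.

#' Build a per-tumor binary mutation matrix
#'
#' Rows are distinct mutations (union over regions), columns are the tumor's
#' regions; an entry is 1 iff the mutation was detected in that region. Rows
#' that would be all zero cannot arise (a mutation enters the union only by
#' being observed somewhere).
#'
#' @param variants Variant tibble for one patient (typically the passing set).
#' @param regions Region set; defaults to the regions present in `variants`.
#' @return Integer matrix with mutation keys (`chrom:pos:ref:alt`) as row
#'   names and regions as column names.
#' @export
mutation_matrix <- function(variants, regions = NULL) {
  if (is.null(regions)) regions <- sort(unique(variants$region_id))
  keys <- sort(unique(mutation_key(variants)))
  m <- matrix(0L, nrow = length(keys), ncol = length(regions),
              dimnames = list(keys, regions))
  if (nrow(variants)) {
    m[cbind(match(mutation_key(variants), keys),
            match(variants$region_id, regions))] <- 1L
  }
  m
}

#' Classify mutations as trunk, branch or private
#'
#' Trunk: present in all regions of the tumor; private: present in exactly
#' one; branch: otherwise (a strict nonempty subset of >= 2 regions). Tumors
#' with a single sequenced region are all-trunk by convention and flagged as
#' excluded from ITH summaries.
#'
#' @param matrix A binary matrix from [mutation_matrix()].
#' @return Tibble `mutation`, `n_regions_present`, `n_regions`, `label`, and
#'   logical `single_region_tumor`.
#' @export
classify_trunk_branch_private <- function(matrix) {
  stopifnot(ncol(matrix) >= 1)
  n_present <- rowSums(matrix)
  n_regions <- ncol(matrix)
  label <- dplyr::case_when(n_present == n_regions ~ "trunk",
                            n_present == 1 ~ "private",
                            TRUE ~ "branch")
  tibble::tibble(mutation = rownames(matrix),
                 n_regions_present = as.integer(n_present),
                 n_regions = n_regions, label = label,
                 single_region_tumor = n_regions == 1)
}

#' Trunk fraction of a labeled mutation set
#' @param labels Output of [classify_trunk_branch_private()].
#' @return Proportion of mutations labeled trunk.
#' @export
trunk_fraction <- function(labels) mean(labels$label == "trunk")

jaccard_sets <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Pairwise mutational Jaccard index between tumor regions
#'
#' For each region pair, the number of shared mutations divided by the size
#' of the union of the two regions' mutation sets; insensitive to the number
#' of regions sequenced, unlike the trunk proportion.
#'
#' @param matrix A binary matrix from [mutation_matrix()].
#' @return List with `pairs` (tibble `region_a`, `region_b`, `jaccard`) and
#'   `mean_jaccard`; both empty/`NA` (and `flagged`) for single-region tumors.
#' @export
mutational_jaccard <- function(matrix) {
  regions <- colnames(matrix)
  if (length(regions) < 2) {
    return(list(pairs = tibble::tibble(region_a = character(),
                                       region_b = character(),
                                       jaccard = double()),
                mean_jaccard = NA_real_, flagged = TRUE))
  }
  cmb <- utils::combn(regions, 2)
  ji <- apply(cmb, 2, function(p) {
    jaccard_sets(rownames(matrix)[matrix[, p[1]] == 1],
                 rownames(matrix)[matrix[, p[2]] == 1])
  })
  pairs <- tibble::tibble(region_a = cmb[1, ], region_b = cmb[2, ],
                          jaccard = ji)
  list(pairs = pairs, mean_jaccard = mean(ji), flagged = FALSE)
}

# ---- Wagner parsimony ------------------------------------------------------

# Rooted binary topologies on a leaf set, enumerated by stepwise addition:
# every tree on k leaves arises by inserting leaf k on one of the 2k-3
# attachment points of a tree on k-1 leaves. Trees are nested lists; a leaf
# is its name.
enumerate_rooted_trees <- function(leaves) {
  trees <- list(leaves[1])
  for (leaf in leaves[-1]) {
    trees <- unlist(lapply(trees, insert_leaf, leaf = leaf),
                    recursive = FALSE)
  }
  trees
}

insert_leaf <- function(tree, leaf) {
  out <- list(list(tree, leaf))        # attach above the current root
  if (!is.character(tree)) {
    for (side in 1:2) {
      for (sub in insert_leaf(tree[[side]], leaf)) {
        t2 <- tree
        t2[[side]] <- sub
        out[[length(out) + 1]] <- t2
      }
    }
  }
  out
}

canonical_encoding <- function(tree) {
  if (is.character(tree)) return(tree)
  kids <- sort(c(canonical_encoding(tree[[1]]), canonical_encoding(tree[[2]])))
  paste0("(", kids[1], ",", kids[2], ")")
}

# Fitch bottom-up over one topology for all unique presence patterns at once.
# States are bitmasks: 1 = absent(0), 2 = present(1), 3 = ambiguous.
fitch_up <- function(tree, patterns) {
  if (is.character(tree)) {
    return(list(set = ifelse(patterns[, tree] == 1L, 2L, 1L),
                count = rep(0L, nrow(patterns)), tree = tree))
  }
  l <- fitch_up(tree[[1]], patterns)
  r <- fitch_up(tree[[2]], patterns)
  inter <- bitwAnd(l$set, r$set)
  disjoint <- inter == 0L
  set <- ifelse(disjoint, bitwOr(l$set, r$set), inter)
  list(set = set, count = l$count + r$count + as.integer(disjoint),
       left = l, right = r)
}

# Top-down minimal-change refinement with the germline state (absent) fixed at
# the root; prefers the parent state when ambiguous, which realizes a
# minimum-change labeling for Fitch sets.
fitch_down <- function(node, parent_state, edge_counts, weights, path) {
  has_parent <- bitwAnd(node$set, parent_state) != 0L
  state <- ifelse(has_parent, parent_state,
                  ifelse(bitwAnd(node$set, 1L) != 0L, 1L, 2L))
  changed <- state != parent_state
  if (any(changed)) {
    edge_counts[[path]] <- sum(weights[changed])
  }
  if (is.null(node$tree)) {
    edge_counts <- fitch_down(node$left, state, edge_counts, weights,
                              paste0(path, "L"))
    edge_counts <- fitch_down(node$right, state, edge_counts, weights,
                              paste0(path, "R"))
  }
  edge_counts
}

#' Exhaustive Wagner-parsimony tree with a germline root
#'
#' Finds, by exhaustive search over all rooted topologies on the tumor's
#' regions with an all-zero germline ancestor above the root, the tree
#' minimizing the total number of character changes (binary presence/absence,
#' reversals allowed, Fitch counting). Ties between equally parsimonious
#' topologies are broken by the lexicographically smallest canonical topology
#' encoding. Per-edge mutation counts come from the minimum-change state
#' assignment that prefers the parental state at ambiguous nodes.
#'
#' @param matrix Binary matrix from [mutation_matrix()]; at most 8 regions
#'   (the exhaustive bound; multi-region studies rarely exceed 3).
#' @return An object of class `parsimony_tree`: list with `topology` (nested
#'   list), `newick` (edge-annotated string), `length` (total changes),
#'   `trunk_count` (changes on the germline edge), `edge_counts` (named
#'   vector by edge path from the root: `"0"` is the germline/trunk edge, then
#'   `"L"`/`"R"` recursively), and `regions`.
#' @export
build_parsimony_tree <- function(matrix) {
  regions <- colnames(matrix)
  n <- length(regions)
  if (n > 8) {
    stop("exhaustive topology search supports at most 8 regions; ",
         "use a heuristic tool for larger trees", call. = FALSE)
  }
  # collapse identical presence patterns
  pat_key <- apply(matrix, 1, paste, collapse = "")
  uniq <- !duplicated(pat_key)
  patterns <- matrix[uniq, , drop = FALSE]
  weights <- as.integer(table(pat_key)[pat_key[uniq]])

  if (n == 1) {
    len <- sum(weights[patterns[, 1] == 1L])
    return(structure(list(topology = regions, newick = sprintf(
      "(%s:%d)germline;", regions, len), length = len, trunk_count = len,
      edge_counts = c("0" = len), regions = regions), class = "parsimony_tree"))
  }

  best <- NULL
  for (tree in enumerate_rooted_trees(regions)) {
    up <- fitch_up(tree, patterns)
    # germline edge: change if "absent" not in the root set
    germ_change <- bitwAnd(up$set, 1L) == 0L
    len <- sum((up$count + as.integer(germ_change)) * weights)
    enc <- canonical_encoding(tree)
    if (is.null(best) || len < best$length ||
        (len == best$length && enc < best$enc)) {
      best <- list(tree = tree, up = up, length = len, enc = enc)
    }
  }
  edge_counts <- fitch_down(best$up, 1L, list(), weights, "0")
  paths <- all_edge_paths(best$tree, "0")
  counts <- setNames(rep(0, length(paths)), paths)
  for (p in names(edge_counts)) counts[p] <- edge_counts[[p]]
  structure(list(topology = best$tree,
                 newick = tree_newick(best$tree, counts),
                 length = best$length,
                 trunk_count = unname(counts["0"]),
                 edge_counts = counts, regions = regions),
            class = "parsimony_tree")
}

all_edge_paths <- function(tree, path) {
  if (is.character(tree)) return(path)
  c(path, all_edge_paths(tree[[1]], paste0(path, "L")),
    all_edge_paths(tree[[2]], paste0(path, "R")))
}

tree_newick <- function(tree, counts) {
  body <- function(node, path) {
    n <- format(as.integer(counts[path]))
    if (is.character(node)) {
      sprintf("%s:%s", node, n)
    } else {
      sprintf("(%s,%s):%s", body(node[[1]], paste0(path, "L")),
              body(node[[2]], paste0(path, "R")), n)
    }
  }
  paste0("(", body(tree, "0"), ")germline;")
}

#' @export
print.parsimony_tree <- function(x, ...) {
  cat(sprintf("<parsimony_tree> %d region(s), length %d (trunk %d)\n  %s\n",
              length(x$regions), x$length, x$trunk_count, x$newick))
  invisible(x)
}

#' @export
tidy.parsimony_tree <- function(x, ...) {
  tibble::tibble(edge = names(x$edge_counts),
                 is_trunk = names(x$edge_counts) == "0",
                 mutations = unname(x$edge_counts))
}

#' @export
glance.parsimony_tree <- function(x, ...) {
  tibble::tibble(n_regions = length(x$regions), length = x$length,
                 trunk_count = x$trunk_count,
                 trunk_fraction = ifelse(x$length > 0,
                                         x$trunk_count / x$length, NA_real_))
}

#' Convert a parsimony tree to an ape `phylo`
#' @param x A `parsimony_tree`.
#' @return An [ape::read.tree()] `phylo` object (germline as root label;
#'   branch lengths are mutation counts).
#' @export
as_phylo <- function(x) {
  stopifnot(inherits(x, "parsimony_tree"))
  ape::read.tree(text = x$newick)
}

# ---- cancer-cell fraction --------------------------------------------------

#' Estimate the cancer-cell fraction of a mutation
#'
#' CCF = VAF * (purity * local_cn + (1 - purity) * 2) / (purity *
#' multiplicity), the usual purity/copy-number adjustment of the variant
#' allele frequency under a normal diploid background. The raw value is
#' retained before clamping to \[0, 1\].
#'
#' @param vaf Variant allele frequency in the (merged) tumor sample.
#' @param purity Tumor purity in (0, 1].
#' @param local_cn Local total copy number (>= 1; default 2).
#' @param multiplicity Mutation copies per carrying cell (default:
#'   re-estimated as the rounded raw CCF when it exceeds 1 and `max_mult`
#'   allows, else 1).
#' @param max_mult Cap for the re-estimated multiplicity (e.g. the major
#'   allele count; default `local_cn`).
#' @return Tibble `ccf_raw`, `multiplicity`, `ccf` (clamped).
#' @export
estimate_ccf <- function(vaf, purity, local_cn = 2, multiplicity = NULL,
                         max_mult = local_cn) {
  if (any(purity <= 0)) stop("purity must be > 0", call. = FALSE)
  stopifnot(all(local_cn >= 1))
  adj <- vaf * (purity * local_cn + (1 - purity) * 2) / purity
  if (is.null(multiplicity)) {
    multiplicity <- ifelse(adj > 1, pmin(pmax(round(adj), 1), max_mult), 1)
  }
  raw <- adj / multiplicity
  tibble::tibble(ccf_raw = raw, multiplicity = multiplicity,
                 ccf = pmin(pmax(raw, 0), 1))
}

#' Merge per-region variant observations to tumor level
#'
#' Emulates variant calling on merged alignments by summing alt-supporting
#' and total read counts per mutation across regions and recomputing the VAF.
#' Log-odds scores are summed across regions (independent evidence), so the
#' tumor-level LOD filter can be applied to the merged calls.
#'
#' @param variants Variant tibble for one patient.
#' @return Tumor-level variant tibble (one row per mutation,
#'   `region_id = "tumor"`).
#' @export
merge_regions <- function(variants) {
  variants |>
    dplyr::group_by(.data$patient_id, .data$chrom, .data$pos, .data$ref,
                    .data$alt, .data$gene, .data$func_class, .data$tnc) |>
    dplyr::summarise(
      t_depth = sum(.data$t_depth), n_depth = max(.data$n_depth),
      t_alt = sum(.data$t_alt), n_vaf = max(.data$n_vaf),
      lod = sum(.data$lod), cadd = dplyr::first(.data$cadd),
      popfreq_esp = dplyr::first(.data$popfreq_esp),
      popfreq_1kg = dplyr::first(.data$popfreq_1kg),
      popfreq_exac = dplyr::first(.data$popfreq_exac),
      .groups = "drop") |>
    dplyr::mutate(t_vaf = ifelse(.data$t_depth > 0,
                                 .data$t_alt / .data$t_depth, 0),
                  region_id = "tumor")
}

# ---- clonal architecture ---------------------------------------------------

#' Cluster cancer-cell fractions into a clonal architecture
#'
#' One-dimensional Gaussian-mixture clustering of per-mutation CCFs with the
#' number of components selected by BIC over 1..`k_max`. Each cluster's
#' cellular prevalence is its mean CCF; mutations in the cluster with the
#' highest cellular prevalence are clonal, all others subclonal. Clustering
#' operates on the raw (pre-clamp) CCFs so that the clonal peak is not
#' squashed against 1. With fewer than 5 mutations a flagged single-cluster
#' fallback is returned.
#'
#' @param ccf Numeric vector of (raw) CCF values for one tumor.
#' @param k_max Maximum number of mixture components (default 5).
#' @return An object of class `clonal_architecture`: list with `assignments`
#'   (tibble `ccf`, `cluster`, `cellular_prevalence`, `clonal`), `clusters`
#'   (tibble `cluster`, `cellular_prevalence`, `n`), `clonal_fraction`, `k`,
#'   and `fallback`.
#' @importFrom mclust Mclust mclustBIC
#' @export
cluster_clonal_architecture <- function(ccf, k_max = 5) {
  stopifnot(length(ccf) >= 1, all(is.finite(ccf)))
  fallback <- length(ccf) < 5 || stats::sd(ccf) < 1e-8
  if (fallback) {
    cl <- rep(1L, length(ccf))
    means <- mean(ccf)
    k <- 1L
  } else {
    fit <- mclust::Mclust(ccf, G = 1:k_max, verbose = FALSE)
    cl <- fit$classification
    means <- as.vector(fit$parameters$mean)
    k <- fit$G
  }
  prevalence <- means[cl]
  clonal_cluster <- which.max(means)
  assignments <- tibble::tibble(ccf = ccf, cluster = as.integer(cl),
                                cellular_prevalence = prevalence,
                                clonal = cl == clonal_cluster)
  clusters <- assignments |>
    dplyr::count(.data$cluster, .data$cellular_prevalence) |>
    dplyr::arrange(dplyr::desc(.data$cellular_prevalence))
  structure(list(assignments = assignments, clusters = clusters,
                 clonal_fraction = mean(assignments$clonal),
                 k = as.integer(k), fallback = fallback),
            class = "clonal_architecture")
}

#' @export
print.clonal_architecture <- function(x, ...) {
  cat(sprintf(
    "<clonal_architecture> %d mutations in %d cluster(s); clonal fraction %.3f%s\n",
    nrow(x$assignments), x$k, x$clonal_fraction,
    if (x$fallback) " [single-cluster fallback]" else ""))
  invisible(x)
}

#' @export
tidy.clonal_architecture <- function(x, ...) x$assignments

#' @export
glance.clonal_architecture <- function(x, ...) {
  tibble::tibble(n_mutations = nrow(x$assignments), k = x$k,
                 clonal_fraction = x$clonal_fraction, fallback = x$fallback)
}
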