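# Packaged reference tables. Both are deterministic synthetic stand-ins built
# in code so the package carries no external data: the signature catalog mimics
# the qualitative structure of the published 30-signature reference (signature
# 4 C>A-heavy as in tobacco smoking, signature 3 near-flat as in HR-deficiency,
# signature 1 C>T at CpG-like contexts) and the gene model anchors real cancer
# and immune gene symbols at synthetic coordinates.

SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' The 96 trinucleotide substitution channels
#'
#' Channel labels follow the conventional 6 x 16 layout: the six
#' pyrimidine-strand substitution classes (C>A, C>G, C>T, T>A, T>C, T>G), each
#' crossed with the 16 flanking-base contexts in alphabetical order. Labels
#' have the form `"A[C>A]A"`.
#'
#' @return Character vector of length 96 in the fixed channel order.
#' @export
#' @examples
#' head(trinucleotide_channels())
trinucleotide_channels <- function() {
  unlist(lapply(SUBSTITUTION_CLASSES, function(cls) {
    ref <- substr(cls, 1, 1)
    as.vector(t(outer(BASES, BASES, function(up, dn) {
      paste0(up, "[", cls, "]", dn)
    })))
  }))
}

#' Reference mutational-signature matrix (synthetic)
#'
#' A deterministic, synthetic 96 x 30 reference catalog of mutational-signature
#' profiles used by both the simulator and the refitting routine. It is a
#' stand-in constructed in code, not the published catalog: signature 4 is
#' concentrated on C>A channels (smoking-like), signature 3 is near-uniform
#' (double-strand-break-repair-defect-like), signature 1 is C>T-dominated, and
#' the remaining columns are distinct smooth pseudo-random profiles. Each
#' column is a probability distribution over the 96 channels.
#'
#' @return A 96 x 30 numeric matrix; rows named by channel, columns
#'   `"Signature.1"` ... `"Signature.30"`; every column sums to 1.
#' @export
#' @examples
#' ref <- reference_signatures()
#' colSums(ref)[1:3]
reference_signatures <- function() {
  ch <- trinucleotide_channels()
  cls <- substr(ch, 3, 5)
  i <- seq_along(ch)
  sig <- matrix(0, nrow = 96, ncol = 30,
                dimnames = list(ch, paste0("Signature.", 1:30)))
  for (s in 1:30) {
    # smooth deterministic pseudo-random base profile, distinct per signature
    raw <- exp(1.6 * sin(0.61 * s * i + s * s) + 0.9 * cos(0.23 * i * (s + 3)))
    sig[, s] <- raw
  }
  # smoking-like: mass on C>A
  sig[, 4] <- ifelse(cls == "C>A", sig[, 4] * 40, sig[, 4] * 0.5)
  # HRD-like: broad and even, with enough structure to stay identifiable
  # against mixtures of the other profiles
  sig[, 3] <- 1 + 0.6 * sin(0.37 * i) + 0.4 * cos(0.11 * i * i)
  sig[, 3] <- sig[, 3] - min(sig[, 3]) + 0.3
  # clock-like: C>T dominated
  sig[, 1] <- ifelse(cls == "C>T", sig[, 1] * 25, sig[, 1] * 0.5)
  sweep(sig, 2, colSums(sig), "/")
}

IFNG_PATHWAY_GENES <- c("IFNGR1", "IFNGR2", "JAK1", "JAK2",
                        "STAT1", "IRF1", "B2M", "IFNG")

ANCHOR_GENES <- tibble::tribble(
  ~gene,     ~chrom, ~role,
  "TP53",    "17",   "TSG",
  "RB1",     "13",   "TSG",
  "PTEN",    "10",   "TSG",
  "NOTCH1",  "9",    "TSG",
  "CREBBP",  "16",   "TSG",
  "EP300",   "22",   "TSG",
  "KMT2D",   "12",   "TSG",
  "MYC",     "8",    "oncogene",
  "MYCL",    "1",    "oncogene",
  "MYCN",    "2",    "oncogene",
  "KRAS",    "12",   "oncogene",
  "EGFR",    "7",    "oncogene",
  "PIK3CA",  "3",    "oncogene",
  "FGFR1",   "8",    "oncogene",
  "SOX2",    "3",    "oncogene",
  "CCNE1",   "19",   "oncogene",
  "IRS2",    "13",   "oncogene",
  "IFNGR1",  "6",    "other",
  "IFNGR2",  "21",   "other",
  "JAK1",    "1",    "other",
  "JAK2",    "9",    "other",
  "STAT1",   "2",    "other",
  "IRF1",    "5",    "other",
  "B2M",     "15",   "other",
  "IFNG",    "12",   "other",
  "HLA-A",   "6",    "other",
  "HLA-B",   "6",    "other",
  "HLA-C",   "6",    "other"
)

#' Default gene model (synthetic coordinates)
#'
#' A deterministic gene model of about 1,000 genes laid out on chromosomes
#' 1-22 with 1-based inclusive coordinates, used for gene-level copy-number
#' and LOH work. Real cancer-gene and IFN-gamma-pathway symbols (TP53, RB1,
#' JAK1, B2M, ...) are anchored at synthetic positions; filler genes are named
#' `GENE0001` onwards. Coordinates are synthetic: the model supports testing
#' and simulation, not annotation of real data (users supply their own model
#' for that).
#'
#' @param n_genes Total number of genes (anchors included). Default 1000.
#' @return Tibble with columns `gene`, `chrom`, `start`, `end`, `role`
#'   (`"oncogene"`, `"TSG"` or `"other"`).
#' @export
#' @examples
#' default_gene_model() |> head()
default_gene_model <- function(n_genes = 1000) {
  stopifnot(n_genes >= nrow(ANCHOR_GENES))
  n_fill <- n_genes - nrow(ANCHOR_GENES)
  fill <- tibble::tibble(
    gene = sprintf("GENE%04d", seq_len(n_fill)),
    chrom = as.character(rep_len(1:22, n_fill)),
    role = "other"
  )
  g <- dplyr::bind_rows(ANCHOR_GENES, fill)
  g <- g[order(g$chrom, g$gene), ]
  # deterministic layout: genes on each chromosome every 1 Mb, 20 kb long
  g <- dplyr::group_by(g, .data$chrom)
  g <- dplyr::mutate(g,
    start = 1e6 * (dplyr::row_number() - 1) + 10001,
    end = .data$start + 19999
  )
  dplyr::ungroup(g)[, c("gene", "chrom", "start", "end", "role")]
}

#' Default gene-role map and hotspot list
#'
#' `default_gene_roles()` returns the gene -> role ("oncogene"/"TSG"/"other")
#' map of the packaged gene model. `default_hotspots()` returns a small
#' synthetic hotspot table (gene + position) of recurrent oncogene mutations
#' used by the cancer-gene classifier.
#'
#' @return A named character vector (roles) or a tibble with columns `gene`,
#'   `pos` (hotspots).
#' @export
default_gene_roles <- function() {
  gm <- default_gene_model()
  setNames(gm$role, gm$gene)
}

#' @rdname default_gene_roles
#' @export
default_hotspots <- function() {
  gm <- default_gene_model()
  onc <- gm[gm$role == "oncogene", ]
  tibble::tibble(gene = onc$gene, pos = onc$start + 500)
}

#' Default IFN-gamma pathway gene set
#'
#' The copy-number-loss burden of interferon-gamma pathway genes is a readout
#' of immune-escape potential. This default set (IFNGR1, IFNGR2, JAK1, JAK2,
#' STAT1, IRF1, B2M, IFNG) is a reconstruction of the commonly used pathway
#' panel and is overridable wherever it is consumed.
#'
#' @return Character vector of gene symbols.
#' @export
default_ifng_genes <- function() IFNG_PATHWAY_GENES
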