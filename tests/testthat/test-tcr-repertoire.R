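# Repertoire metrics, overlap, sharing classes, tumor-vs-adjacent contrast.

test_that("clonality matches the entropy formula and its conventions", {
  expect_equal(repertoire_metrics(make_clonotypes(c(0.5, 0.5)))$clonality, 0)
  m <- repertoire_metrics(make_clonotypes(c(0.9, 0.1)))
  expect_equal(m$clonality, 1 - 0.325083 / log(2), tolerance = 1e-5)
  expect_equal(m$clonality, 0.531004, tolerance = 1e-5)
  # single clone: clonality 0 by convention
  expect_equal(repertoire_metrics(make_clonotypes(1))$clonality, 0)
  # density = templates per input cell
  d <- repertoire_metrics(make_clonotypes(c(0.6, 0.4), total = 100,
                                          input_cells = 1000))
  expect_equal(d$density, 0.1)
  expect_identical(d$richness, 2L)
  # unusable input cells: density missing, the rest computed
  d2 <- repertoire_metrics(make_clonotypes(c(0.6, 0.4), input_cells = 0))
  expect_true(is.na(d2$density))
  expect_identical(d2$richness, 2L)
})

test_that("overlap metrics hit the closed-form values", {
  a <- make_clonotypes(c(0.5, 0.5), names = c("x", "y"), region = "R1")
  b <- make_clonotypes(c(0.5, 0.5), names = c("y", "z"), region = "R2")
  o <- overlap_metrics(a, b)
  expect_equal(o$jaccard, 1 / 3)
  expect_equal(o$morisita, 0.5)       # hand evaluation of Morisita-Horn
  expect_equal(o$top20_shared, 0.5)

  same <- overlap_metrics(a, a)
  expect_equal(unlist(same[c("jaccard", "morisita", "top20_shared")]),
               c(jaccard = 1, morisita = 1, top20_shared = 1))

  disj <- overlap_metrics(a, make_clonotypes(c(0.5, 0.5),
                                             names = c("u", "v")))
  expect_equal(unlist(disj[c("jaccard", "morisita", "top20_shared")]),
               c(jaccard = 0, morisita = 0, top20_shared = 0))
})

test_that("clonality and Morisita-Horn are scale-invariant; overlap symmetric", {
  set.seed(5)
  f <- sort(runif(40), decreasing = TRUE)
  a <- make_clonotypes(f / sum(f), total = 1000)
  a10 <- a
  a10$clones$templates <- a10$clones$templates * 10L
  a10$total_templates <- a10$total_templates * 10
  expect_equal(repertoire_metrics(a)$clonality,
               repertoire_metrics(a10)$clonality)

  g <- sort(runif(40), decreasing = TRUE)
  b <- make_clonotypes(g / sum(g), total = 1000,
                       names = c(paste0("seq", 21:40), paste0("new", 1:20)))
  o1 <- overlap_metrics(a, b)
  o2 <- overlap_metrics(b, a)
  expect_equal(o1$jaccard, o2$jaccard)
  expect_equal(o1$morisita, o2$morisita)
  expect_equal(o1$top20_shared, o2$top20_shared)

  b10 <- b
  b10$clones$templates <- b10$clones$templates * 7L
  expect_equal(overlap_metrics(a, b10)$morisita, o1$morisita)
})

test_that("sharing classes partition the clonotype union", {
  mk <- function(names, region) {
    make_clonotypes(rep(1 / length(names), length(names)), names = names,
                    region = region)
  }
  # 1 ubiquitous, 19 in two regions, 80 private among 3 regions
  ubiq <- "u1"
  two <- paste0("t", 1:19)
  priv <- split(paste0("p", 1:80), rep(1:3, length.out = 80))
  tabs <- list(mk(c(ubiq, two, priv[[1]]), "R1"),
               mk(c(ubiq, two, priv[[2]]), "R2"),
               mk(c(ubiq, priv[[3]]), "R3"))
  sc <- sharing_classes(tabs)
  expect_equal(sc$shared_all, 0.01)
  expect_equal(sc$intermediate, 0.19)
  expect_equal(sc$single_region, 0.80)
  expect_equal(sc$shared_all + sc$intermediate + sc$single_region, 1)

  all_shared <- sharing_classes(list(mk(two, "R1"), mk(two, "R2")))
  expect_equal(all_shared$shared_all, 1)
  disjoint <- sharing_classes(list(mk(paste0("a", 1:5), "R1"),
                                   mk(paste0("b", 1:5), "R2")))
  expect_equal(disjoint$single_region, 1)
  expect_error(sharing_classes(tabs[1]), "single region")
})

test_that("downsampling templates never increases richness", {
  set.seed(9)
  f <- as.vector(rmultinom(1, 2000, seq_len(100)^-1))
  tab <- make_clonotypes(f[f > 0] / sum(f), total = sum(f))
  base_rich <- repertoire_metrics(tab)$richness
  expanded <- rep(tab$clones$rearrangement, tab$clones$templates)
  for (i in 1:50) {
    sub <- sample(expanded, 500)
    counts <- table(sub)
    subtab <- make_clonotypes(as.vector(counts) / sum(counts),
                              names = names(counts), total = 500)
    expect_lte(repertoire_metrics(subtab)$richness, base_rich)
  }
})

test_that("tumor versus adjacent contrast pairs patients and detects shifts", {
  mk_metrics <- function(n_pat, tumor_density, adj_density, seed) {
    set.seed(seed)
    dplyr::bind_rows(lapply(seq_len(n_pat), function(i) {
      tibble::tibble(
        patient_id = sprintf("P%02d", i),
        region_id = c("R1", "R2", adjacent_lung_region()),
        density = c(tumor_density * runif(2, 0.5, 1.5),
                    adj_density * runif(1, 0.5, 1.5)),
        richness = c(round(300 * runif(2, 0.5, 1.5)),
                     round(900 * runif(1, 0.5, 1.5))),
        clonality = c(runif(2, 0, 0.1), runif(1, 0.3, 0.6)),
        total_templates = 1000)
    }))
  }
  hits <- vapply(1:20, function(r) {
    m <- mk_metrics(16, 0.04, 0.2, seed = 300 + r)
    out <- tumor_vs_adjacent_contrast(m)
    out$p_value[out$metric == "density"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # identical paired values give the null p = 1
  ident <- mk_metrics(8, 0.1, 0.1, seed = 1)
  ident$density <- 0.1
  ident$richness <- 500
  ident$clonality <- 0.05
  out_id <- tumor_vs_adjacent_contrast(ident)
  expect_true(all(out_id$p_value > 0.9))

  expect_error(tumor_vs_adjacent_contrast(mk_metrics(2, 0.04, 0.2, 1)),
               "fewer than 3")
})
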