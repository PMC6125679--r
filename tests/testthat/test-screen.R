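test_that("normalize_sf centres NT wells at 1 and is scale invariant", {
  tbl <- make_sf_table(sample_sf = c(0.05, 0.2), nt_sf = c(0.10, 0.10, 0.10))
  norm <- normalize_sf(tbl)
  expect_equal(norm$normalized_sf[norm$role == "nt_control"], rep(1, 3))
  expect_equal(norm$normalized_sf[norm$target == "G001"], 0.5)

  # multiplying every sf in a run by a constant changes nothing
  scaled <- dplyr::mutate(tbl, sf = sf * 3.7)
  expect_equal(normalize_sf(scaled)$normalized_sf, norm$normalized_sf)
})

test_that("normalize_sf fails on runs without NT wells", {
  tbl <- make_sf_table(c(0.05), c(0.1, 0.1)) |>
    dplyr::filter(role == "sample")
  expect_error(normalize_sf(tbl), "without non-targeting")
})

test_that("r_score evaluates the printed formula and ranks ascending", {
  # NT normalized {0.9, 1.0, 1.1}: MAD_mean = 0.0667, gene at 0.8 scores -3
  tbl <- make_sf_table(sample_sf = c(0.8, 1.0, 1.3),
                       nt_sf = c(0.9, 1.0, 1.1))
  rs <- r_score(normalize_sf(tbl, location = "mean"))
  g <- rs[rs$role == "sample", ]
  expect_equal(g$r_score[g$gene_id == "G001"], -3, tolerance = 1e-10)
  expect_equal(g$r_score[g$gene_id == "G002"], 0, tolerance = 1e-10)
  # most negative score takes rank 1 (ascending ranking)
  expect_equal(g$rank[which.min(g$r_score)], 1)
  expect_equal(sort(g$rank), 1:3)
})

test_that("r_score matches the independent one-line oracle on random tables", {
  set.seed(101)
  for (case in 1:100) {
    n <- sample(2:20, 1)
    tbl <- make_sf_table(sample_sf = runif(n, 0.2, 1.6),
                         nt_sf = runif(sample(3:8, 1), 0.7, 1.3))
    norm <- normalize_sf(tbl)
    rs <- r_score(norm)
    nt_norm <- norm$normalized_sf[norm$role == "nt_control"]
    g <- rs[rs$role == "sample", ]
    expect_equal(g$r_score,
                 rscore_oracle(g$normalized_sf, nt_norm),
                 tolerance = 1e-12)
  }
})

test_that("r_score errors on degenerate NT controls", {
  tbl <- make_sf_table(c(0.5), c(0.1, 0.1, 0.1))
  expect_error(r_score(normalize_sf(tbl)), "degenerate")
  tbl1 <- make_sf_table(c(0.5), c(0.1))
  expect_error(r_score(normalize_sf(tbl1)), "< 2 NT")
})

test_that("rank product is the geometric mean of per-run ranks", {
  rs <- tibble::tibble(
    run_id = rep(c("run1", "run2"), each = 3),
    gene_id = rep(c("A", "B", "C"), 2),
    role = "sample",
    normalized_sf = NA_real_,
    r_score = NA_real_,
    rank = c(1, 2, 3, 2, 1, 3)
  )
  rp <- rank_product(rs)
  expect_equal(rp$rp[rp$gene_id == "A"], sqrt(2))
  expect_equal(rp$rp[rp$gene_id == "B"], sqrt(2))
  expect_equal(rp$rp[rp$gene_id == "C"], 3)
  # invariant to run order
  rs_rev <- dplyr::arrange(rs, dplyr::desc(run_id))
  expect_equal(rank_product(rs_rev)$rp, rp$rp)
  # missing gene errors
  expect_error(rank_product(rs[-1, ]), "missing")
})

test_that("rank product equals brute force on random small instances", {
  set.seed(7)
  for (case in 1:20) {
    n <- sample(2:6, 1)
    k <- sample(2:3, 1)
    ranks <- replicate(k, sample(n))
    rs <- tibble::tibble(
      run_id = rep(sprintf("run%d", 1:k), each = n),
      gene_id = rep(sprintf("g%d", 1:n), k),
      role = "sample", normalized_sf = NA_real_, r_score = NA_real_,
      rank = as.vector(ranks)
    )
    rp <- rank_product(rs)
    brute <- apply(ranks, 1, function(r) prod(r)^(1 / k))
    expect_equal(rp$rp[match(sprintf("g%d", 1:n), rp$gene_id)], brute)
  }
})

test_that("exhaustive rank-product p-values match direct enumeration", {
  # 3 genes, 2 runs, gene with ranks (1,2): p = P(r1*r2 <= 2) = 3/9
  rs <- tibble::tibble(
    run_id = rep(c("run1", "run2"), each = 3),
    gene_id = rep(c("A", "B", "C"), 2),
    role = "sample", normalized_sf = NA_real_, r_score = NA_real_,
    rank = c(1, 2, 3, 2, 1, 3)
  )
  rp <- rank_product_pvalues(rank_product(rs))
  expect_identical(attr(rp, "p_method"), "exhaustive")
  expect_equal(rp$p_perm[rp$gene_id == "A"], 3 / 9)
  # worst gene in every run has p = 1
  expect_equal(rp$p_perm[rp$gene_id == "C"], 1)
})

test_that("Monte-Carlo p-values converge to the exhaustive values", {
  set.seed(5)
  n <- 5; k <- 2
  ranks <- replicate(k, sample(n))
  rs <- tibble::tibble(
    run_id = rep(sprintf("run%d", 1:k), each = n),
    gene_id = rep(sprintf("g%d", 1:n), k),
    role = "sample", normalized_sf = NA_real_, r_score = NA_real_,
    rank = as.vector(ranks)
  )
  rp <- rank_product(rs)
  exact <- rank_product_pvalues(rp)
  mc <- rank_product_pvalues(rp, n_permutations = 4000, seed = 9,
                             exhaustive_limit = 0)
  expect_identical(attr(mc, "p_method"), "permutation")
  # binomial 3 s.e. of the MC estimate around the exact value
  tol <- 3 * sqrt(exact$p_perm * (1 - exact$p_perm) / 4000) + 2 / 4000
  expect_true(all(abs(mc$p_perm - exact$p_perm) <= tol))
})

test_that("Z-factor matches the closed form and its symmetries", {
  # two-point groups with exact means and sds
  d <- 0.05 / sqrt(2)
  neg <- c(1 - d, 1 + d)   # mean 1.0, sd 0.05
  pos <- c(0.4 - d, 0.4 + d) # mean 0.4, sd 0.05
  z <- z_factor(neg, pos)
  expect_equal(z$z_factor, 0.5, tolerance = 1e-12)
  expect_equal(z$mu_neg, 1)
  expect_equal(z$sd_pos, 0.05)
  # zero variance: perfect assay
  expect_equal(z_factor(c(1, 1), c(0.4, 0.4))$z_factor, 1)
  # label swap leaves z unchanged
  expect_equal(z_factor(pos, neg)$z_factor, z$z_factor)
  expect_error(z_factor(c(1, 1), c(1, 1)), "undefined")
  expect_error(z_factor(1, c(0.4, 0.5)), ">= 2 wells")
})

test_that("select_top_hits is deterministic with documented tie-breaks", {
  ranking <- tibble::tibble(
    gene_id = c("B", "A", "C", "D"),
    rp = c(2, 2, 1, 3),
    ranks = list(c(2, 2), c(1, 4), c(1, 1), c(3, 3))
  )
  # C first (rp 1); A before B on equal rp: avg rank 2.5 vs 2 -> B first
  expect_equal(select_top_hits(ranking, 3), c("C", "B", "A"))
  expect_equal(select_top_hits(ranking, 4), c("C", "B", "A", "D"))
  expect_equal(select_top_hits(ranking, 0), character(0))
  expect_error(select_top_hits(ranking, 5), "exceeds")
  # pure lexicographic tie-break when scores and ranks tie
  tied <- tibble::tibble(gene_id = c("Z", "Y"), r_score = c(-1, -1))
  expect_equal(select_top_hits(tied, 2), c("Y", "Z"))
})

test_that("NT r-scores have mean zero under mean-location normalization", {
  set.seed(88)
  # per-well NT scores: give each NT well its own target id so wells are
  # not aggregated, with a separate NT pool providing the reference
  nt_sf <- 0.1 * exp(rnorm(12, 0, 0.1))
  tbl <- make_sf_table(sample_sf = numeric(0), nt_sf = nt_sf)
  norm <- normalize_sf(tbl, location = "mean")
  nt_norm <- norm$normalized_sf[norm$role == "nt_control"]
  scores <- rscore_oracle(nt_norm, nt_norm)
  expect_equal(mean(scores), 0, tolerance = 1e-12)
  # the aggregated NT row of r_score() is exactly zero under mean location
  rs <- r_score(norm)
  expect_equal(rs$r_score[rs$gene_id == "NT"], 0, tolerance = 1e-12)
})
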