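test_that("make_precision_matrix honors densities and topology", {
  # zero densities: identity-like diagonal matrix, empty truth
  pm0 <- make_precision_matrix(precision_spec(
    c(A = 4, B = 4), topology = "random", within_kingdom_density = 0,
    cross_kingdom_density = 0))
  expect_equal(nrow(pm0$truth), 0)
  expect_true(all(pm0$omega[upper.tri(pm0$omega)] == 0))
  expect_true(all(diag(pm0$omega) > 0))

  # band, bandwidth 1, 5 taxa in one block: exactly the 4 adjacent pairs
  pm_band <- make_precision_matrix(precision_spec(
    c(A = 5, B = 2), topology = "band", bandwidth = 1,
    cross_kingdom_density = 0))
  adjacent <- edge_key(paste0("A_", 1:4), paste0("A_", 2:5))
  in_a <- grepl("^A", pm_band$truth$taxon_a)
  expect_setequal(edge_key(pm_band$truth$taxon_a[in_a],
                           pm_band$truth$taxon_b[in_a]),
                  adjacent)
  expect_equal(sum(grepl("^B", pm_band$truth$taxon_a) |
                     grepl("^B", pm_band$truth$taxon_b)), 1)  # B band edge

  # random topology: requested density within one edge
  spec <- precision_spec(c(A = 10, B = 10), topology = "random",
                         within_kingdom_density = 0.2,
                         cross_kingdom_density = 0.1, seed = 5)
  pm <- make_precision_matrix(spec)
  kingdom_of <- function(x) sub("_.*", "", x)
  within <- kingdom_of(pm$truth$taxon_a) == kingdom_of(pm$truth$taxon_b)
  expect_lte(abs(sum(within) - 0.2 * 2 * choose(10, 2)), 1)
  expect_lte(abs(sum(!within) - 0.1 * 100), 1)
})

test_that("precision matrices are symmetric positive definite with capped condition", {
  for (topo in c("band", "cluster", "random")) {
    pm <- make_precision_matrix(precision_spec(
      c(A = 8, B = 8, C = 6), topology = topo,
      within_kingdom_density = 0.5, cross_kingdom_density = 0.05,
      condition_cap = 50, seed = 11))
    expect_true(isSymmetric(pm$omega))
    ev <- eigen(pm$omega, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)                        # eigendecomposition oracle
    expect_lte(max(ev) / min(ev), 50 + 1e-8)
    # support is exactly the truth edge set
    idx <- which(pm$omega != 0 & upper.tri(pm$omega), arr.ind = TRUE)
    support <- edge_key(rownames(pm$omega)[idx[, 1]],
                        rownames(pm$omega)[idx[, 2]])
    expect_setequal(support, edge_key(pm$truth$taxon_a, pm$truth$taxon_b))
    # association sign is the opposite of the precision entry's sign
    omega_entries <- pm$omega[cbind(pm$truth$taxon_a, pm$truth$taxon_b)]
    expect_equal(pm$truth$sign, -sign(omega_entries))
  }
})

test_that("precision_spec validates its arguments", {
  expect_error(precision_spec(c(A = 5)), "2 kingdoms")
  expect_error(precision_spec(c(A = 1, B = 5)), "2 taxa")
  expect_error(precision_spec(c(A = 5, B = 5), within_kingdom_density = 1.2),
               "0, 1")
  expect_error(precision_spec(c(A = 5, B = 5), condition_cap = 0.5),
               "condition_cap")
})

test_that("sample_counts draws seeded logistic-normal multinomial counts", {
  pm <- make_precision_matrix(precision_spec(c(A = 5, B = 5), seed = 2))
  x <- sample_counts(pm$omega, n_samples = 6, depths = 1000, seed = 9)
  expect_equal(unname(colSums(x)), rep(1000, 6))
  expect_identical(x, sample_counts(pm$omega, 6, 1000, seed = 9))
  x2 <- sample_counts(pm$omega, 6, 1000, seed = 10)
  expect_false(identical(x, x2))
  # non-positive-definite precision rejected
  bad <- diag(4); bad[1, 2] <- bad[2, 1] <- 2
  expect_error(sample_counts(bad, 3, 100), "positive definite")
})

test_that("identity precision gives uniform mean relative abundances", {
  # Monte-Carlo oracle at large n: each of 10 taxa averages 0.1
  x <- sample_counts(diag(10), n_samples = 5000, depths = 5000, seed = 4)
  rel <- rowMeans(sweep(x, 2, colSums(x), `/`))
  se <- apply(sweep(x, 2, colSums(x), `/`), 1, sd) / sqrt(5000)
  expect_true(all(abs(rel - 0.1) < 3 * se))
})

test_that("sample_plant_table links species to latent abundances", {
  pm <- make_precision_matrix(precision_spec(c(A = 5, B = 5), seed = 2))
  x <- sample_counts(pm$omega, n_samples = 500, depths = 500, seed = 5)
  latent <- attr(x, "latent")

  # link strength 0: independence (point-biserial r within noise of 0)
  p0 <- sample_plant_table(4, 500, latent = latent[, 1, drop = FALSE],
                           link_strength = 0, seed = 6)
  expect_true(all(p0 %in% c(0L, 1L)))
  expect_lt(abs(cor(p0[1, ], latent[, 1])), 3 / sqrt(500))

  # strong link: correlation with the linked taxon's latent value > 0.5
  p1 <- sample_plant_table(4, 500, latent = latent[, 1, drop = FALSE],
                           link_strength = 4, seed = 6)
  expect_gt(cor(p1[1, ], latent[, 1]), 0.5)

  expect_identical(p1, sample_plant_table(4, 500,
                                          latent = latent[, 1, drop = FALSE],
                                          link_strength = 4, seed = 6))
})

test_that("sample_environment plants a gradient and collinear pairs", {
  env <- sample_environment(100, 5, gradient_effect = 2,
                            collinear_pairs = 1, seed = 3)
  expect_equal(dim(env), c(100, 6))
  r <- cor(env)
  diag(r) <- 0
  expect_gt(max(abs(r)), 0.7)  # the planted duplicate pair
  expect_gt(abs(cor(env[, 1], attr(env, "gradient"))), 0.9)

  # null case: no variable tracks the gradient
  env0 <- sample_environment(200, 5, gradient_effect = 0,
                             collinear_pairs = 0, seed = 3)
  rg <- abs(cor(env0, attr(env0, "gradient")))
  expect_true(all(rg < 4 / sqrt(200)))

  expect_identical(env, sample_environment(100, 5, 2, 1, seed = 3))
})

test_that("make_synthetic_dataset assembles a consistent world", {
  ds <- tiny_dataset(seed = 8)
  expect_s3_class(ds, "synthetic_dataset")
  ids <- colnames(ds$counts[[1]]$counts)
  expect_identical(colnames(ds$plant_table), ids)
  expect_identical(rownames(ds$environment), ids)
  taxa <- unlist(lapply(ds$counts, function(t) rownames(t$counts)))
  expect_true(all(ds$truth$taxon_a %in% taxa))
  expect_true(all(ds$truth$taxon_b %in% taxa))
  # bit-reproducible
  ds2 <- tiny_dataset(seed = 8)
  expect_identical(lapply(ds$counts, `[[`, "counts"),
                   lapply(ds2$counts, `[[`, "counts"))
  expect_identical(ds$plant_table, ds2$plant_table)
})
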