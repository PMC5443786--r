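test_that("Bray-Curtis handles boundary and hand-computed cases", {
  expect_equal(bray_curtis(c(3, 2, 1), c(3, 2, 1)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 5)), 1)
  expect_equal(bray_curtis(c(1, 1, 0), c(0, 1, 1)), 0.5)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  set.seed(19)
  for (i in 1:20) {
    x <- rpois(6, 5); y <- rpois(6, 5)
    if (sum(x + y) == 0) next
    d <- bray_curtis(x, y)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, bray_curtis(y, x))
  }
  # matrix form agrees with the pairwise definition
  tab <- tibble::tibble(otu_id = c("a", "b", "c"),
                        s1 = c(1L, 1L, 0L), s2 = c(0L, 1L, 1L),
                        s3 = c(2L, 0L, 0L))
  D <- as.matrix(bray_curtis_matrix(tab))
  expect_equal(D["s1", "s2"], 0.5)
  expect_equal(D["s1", "s3"], bray_curtis(c(1, 1, 0), c(2, 0, 0)))
})

test_that("NMDS embeds representable configurations at ~zero stress", {
  x <- seq(0, 1, length.out = 8)
  D <- as.matrix(dist(cbind(x, 0)))
  dimnames(D) <- list(paste0("s", 1:8), paste0("s", 1:8))
  fit <- suppressWarnings(nmds(D, seed = 4))
  expect_lt(fit$stress, 1e-3)
  expect_equal(fit$shepard_r, 1, tolerance = 1e-6)
  expect_equal(fit$coordinates$sample, paste0("s", 1:8))
  # determinism
  fit2 <- suppressWarnings(nmds(D, seed = 4))
  expect_identical(fit$stress, fit2$stress)
  expect_identical(fit$coordinates, fit2$coordinates)
  expect_error(nmds(matrix(0, 2, 2)), "3 samples")
})

test_that("duplicate samples land on coincident NMDS coordinates", {
  set.seed(20)
  tab <- tibble::tibble(otu_id = paste0("o", 1:10),
                        s1 = rpois(10, 20), s2 = rpois(10, 20),
                        s3 = rpois(10, 20))
  tab$s4 <- tab$s1
  D <- bray_curtis_matrix(tab)
  fit <- suppressWarnings(nmds(D, seed = 5))
  co <- as.matrix(fit$coordinates[, -1])
  expect_lt(sqrt(sum((co[1, ] - co[4, ])^2)), 0.05 * max(dist(co)))
})

test_that("Shepard correlation reflects embedding quality and sign", {
  co <- cbind(c(0, 1, 2), c(0, 0, 0))
  expect_equal(shepard_correlation(dist(co), co), 1)
  # anti-ordered: input dissimilarities reversed relative to distances
  D <- matrix(c(0, 3, 1,
                3, 0, 2,
                1, 2, 0), 3, 3)
  co2 <- cbind(c(0, 0.5, 3), 0)  # near pair has the largest dissimilarity
  expect_lt(shepard_correlation(D, co2), 0)
})

test_that("internal NB fits agree with glm.nb on both design paths", {
  md <- toy_metadata()
  set.seed(21)
  y <- rnbinom(nrow(md), mu = 25, size = 2)
  # saturated single-factor design (group-mean path)
  X1 <- model.matrix(~stage, md)
  f1 <- smdiv:::nb_fit(y, X1)
  g1 <- MASS::glm.nb(y ~ stage, data = md)
  expect_equal(f1$loglik, as.numeric(logLik(g1)), tolerance = 1e-5)
  expect_equal(f1$theta, g1$theta, tolerance = 1e-3)
  # additive two-factor design (IRLS path)
  X2 <- model.matrix(~site + stage, md)
  f2 <- smdiv:::nb_fit(y, X2)
  g2 <- MASS::glm.nb(y ~ site + stage, data = md)
  expect_equal(f2$loglik, as.numeric(logLik(g2)), tolerance = 1e-4)
  expect_equal(f2$theta, g2$theta, tolerance = 1e-2)
})

test_that("differential test demands two levels per factor", {
  md <- toy_metadata(n_sites = 1, n_stages = 2)
  tab <- tibble::tibble(otu_id = "o1",
                        !!!setNames(as.list(rep(5L, nrow(md))), md$sample_id))
  expect_error(fit_differential(tab, md, factors = "site"), "single level")
})

test_that("planted stage effects surface as small bootstrap p-values", {
  md <- toy_metadata()
  set.seed(22)
  n_otu <- 15; shifted <- 1:3  # 20% of OTUs carry a 4-fold stage effect
  sen <- md$stage == "senescence"
  m <- t(sapply(seq_len(n_otu), function(i) {
    mu <- rep(30, nrow(md))
    if (i %in% shifted) mu[sen] <- mu[sen] / 4
    rnbinom(nrow(md), mu = mu, size = 5)
  }))
  dimnames(m) <- list(paste0("o", seq_len(n_otu)), md$sample_id)
  tab <- dplyr::bind_cols(tibble::tibble(otu_id = rownames(m)),
                          tibble::as_tibble(m))
  fit <- fit_differential(tab, md, factors = "stage", n_boot = 99, seed = 6)
  po <- tidy(fit)
  expect_true(all(po$converged))
  truth <- po$otu_id %in% paste0("o", shifted)
  auc <- suppressWarnings(
    as.numeric(wilcox.test(-po$p_boot[truth], -po$p_boot[!truth])$statistic) /
      (sum(truth) * sum(!truth)))
  expect_gt(auc, 0.8)
  expect_lt(glance(fit)$p_boot, 0.05)  # community-level signal
})

test_that("Spearman correlation pipeline applies DA, abundance and pairing filters", {
  md <- toy_metadata()
  samples <- md$sample_id
  base <- seq_len(length(samples))
  sm_tab <- tibble::tibble(otu_id = c("sm1", "sm2"),
                           !!!setNames(lapply(seq_along(samples), function(j)
                             c(base[j], rev(base)[j])), samples))
  mk_tab <- tibble::tibble(otu_id = c("mk1", "mk2", "mk3"),
                           !!!setNames(lapply(seq_along(samples), function(j)
                             c(base[j], base[j], 100L)), samples))
  fake_diff <- function(ids) {
    structure(list(per_otu = tibble::tibble(
      otu_id = ids, factor = "stage", lrt = 1,
      p_boot = 0.001, p_adj = 0.001, converged = TRUE)),
      class = "smdiv_diff")
  }
  tax <- tibble::tibble(otu_id = c("mk1", "mk2", "mk3"),
                        phylum = c("Firmicutes", "Bacteroidetes",
                                   "Firmicutes"),
                        genus = c("Bacillus", "Flavobacterium",
                                  "Paenibacillus"))
  out <- correlate_differential(fake_diff(c("sm1", "sm2")),
                                fake_diff(c("mk1", "mk2", "mk3")),
                                sm_tab, mk_tab, tax, sm_domain = "ACP",
                                min_genus_abundance = 0.001)
  # Bacteroidetes marker OTUs are excluded for ACP by the pairing rule
  expect_false("mk2" %in% out$otu_marker)
  expect_equal(out$rho[out$otu_sm == "sm1" & out$otu_marker == "mk1"], 1)
  expect_equal(out$rho[out$otu_sm == "sm2" & out$otu_marker == "mk1"], -1)
  # constant marker mk3 gives NA rho; the 1% genus filter can remove it
  out2 <- correlate_differential(fake_diff("sm1"), fake_diff("mk1"),
                                 sm_tab, mk_tab, tax, sm_domain = "ACP",
                                 min_genus_abundance = 0.9)
  expect_equal(nrow(out2), 0L)
  expect_error(correlate_differential(fake_diff("sm1"), fake_diff("mk1"),
                                      sm_tab[, 1:3], mk_tab[, 1:3], tax),
               "shared samples")
})
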