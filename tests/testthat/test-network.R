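test_that("adjacency applies the soft-threshold transform", {
  # three samples giving exact correlations 1, -1 and -0.5
  expr <- rbind(x = c(1, 2, 3), y = c(3, 2, 1),
                u = c(1, 0, -1), v = c(-1, 1, 0))
  a <- adjacency_matrix(expr, power = 2)
  expect_equal(unname(a["x", "x"]), 1)
  expect_equal(unname(a["x", "y"]), 1)      # |cor| = 1 at any power
  expect_equal(unname(a["u", "v"]), 0.25)   # |-0.5|^2
  s <- adjacency_matrix(expr, power = 1, signed = TRUE)
  expect_equal(unname(s["x", "y"]), 0)      # signed: (1 - 1)/2
  expect_true(isSymmetric(a))
  expect_true(all(a >= 0 & a <= 1))
  expect_error(adjacency_matrix(expr[, 1:2], 2), "3 samples")
})

test_that("TOM matches hand and naive-loop oracles", {
  # 3-node hand-worked case
  a <- matrix(c(1, .5, .4, .5, 1, .2, .4, .2, 1), 3, 3)
  tom <- topological_overlap(a)
  # TOM_12 = (l + a)/(min(k) + 1 - a) with l = .4*.2, k1 = .9, k2 = .7
  expect_equal(tom[1, 2], (0.4 * 0.2 + 0.5) / (0.7 + 1 - 0.5))
  expect_equal(tom, naive_tom(a), tolerance = 1e-12)

  # unconnected pair with no shared neighbors
  a0 <- diag(4); a0[1, 2] <- a0[2, 1] <- 0
  expect_equal(topological_overlap(a0)[1, 2], 0)
  # clique
  a1 <- matrix(1, 5, 5)
  expect_true(all(topological_overlap(a1) == 1))

  # random instances against the naive triple loop
  set.seed(9)
  for (rep in 1:3) {
    expr <- matrix(rnorm(12 * 20), 12,
                   dimnames = list(paste0("g", 1:12), NULL))
    tomr <- topological_overlap(adjacency_matrix(expr, 6))
    expect_equal(unname(tomr), naive_tom(adjacency_matrix(expr, 6)),
                 tolerance = 1e-12)
    expect_true(isSymmetric(unname(tomr)))
    expect_true(all(tomr >= 0 & tomr <= 1))
    expect_true(all(diag(tomr) == 1))
  }
  expect_error(topological_overlap(matrix(runif(9), 3)), "symmetric")
})

test_that("average-linkage merge heights match a naive reference", {
  set.seed(4)
  expr <- matrix(rnorm(10 * 15), 10)
  d <- 1 - topological_overlap(adjacency_matrix(expr, 6))
  hc <- hclust(as.dist(d), method = "average")
  expect_equal(hc$height, naive_average_linkage_heights(d),
               tolerance = 1e-10)
})

test_that("perfect blocks cluster exactly; noise goes unassigned", {
  # three perfectly correlated blocks, zero cross-adjacency
  a <- matrix(0, 15, 15, dimnames = list(paste0("g", 1:15), paste0("g", 1:15)))
  for (b in 0:2) a[b * 5 + 1:5, b * 5 + 1:5] <- 1
  part <- cluster_modules(1 - topological_overlap(a), min_module_size = 4)
  expect_identical(attr(part, "n_modules"), 3L)
  expect_equal(adjusted_rand_index(part, rep(1:3, each = 5)), 1)

  # i.i.d. noise with min_module_size > n/2: everything lands in module 0
  set.seed(7)
  noise <- matrix(rnorm(30 * 25), 30,
                  dimnames = list(paste0("g", 1:30), NULL))
  dn <- 1 - topological_overlap(adjacency_matrix(noise, 6))
  pn <- cluster_modules(dn, min_module_size = 16)
  expect_true(all(pn == 0L))

  # determinism
  expect_identical(cluster_modules(dn, 16), pn)
  # degenerate dissimilarity warns
  deg <- matrix(0.5, 6, 6); diag(deg) <- 0
  dimnames(deg) <- list(paste0("g", 1:6), paste0("g", 1:6))
  expect_warning(cluster_modules(deg, 2), "degenerate")
})

test_that("planted modules are recovered with high agreement", {
  cfg <- sim_config(seed = 31L)
  co <- generate_cohort(cfg)
  tom <- topological_overlap(adjacency_matrix(co$expr, 6))
  part <- cluster_modules(1 - tom)
  ari <- adjusted_rand_index(part, co$truth$modules)
  expect_gte(ari, 0.9)
  expect_equal(ari, ari_oracle(part, co$truth$modules), tolerance = 1e-12)
})

test_that("soft-threshold choice follows the scale-free fit rule", {
  set.seed(12)
  expr <- matrix(rnorm(40 * 30), 40,
                 dimnames = list(paste0("g", 1:40), NULL))
  # single candidate is returned untouched
  expect_equal(as.integer(suppressWarnings(
    pick_soft_threshold(expr, candidate_powers = 6))), 6L)

  # block cohort: selection matches an independent re-implementation
  co <- generate_cohort(sim_config(seed = 17L))
  p_pkg <- suppressWarnings(pick_soft_threshold(co$expr, 1:12))
  p_ref <- reference_power_choice(co$expr, 1:12, 0.8)
  expect_equal(as.integer(p_pkg), as.integer(p_ref))

  # pure noise exercises the warning path and returns the max-fit power
  set.seed(12)
  noise <- matrix(rnorm(400 * 40), 400,
                  dimnames = list(paste0("n", 1:400), NULL))
  expect_warning(p_n <- pick_soft_threshold(noise, 1:8), "scale-free")
  fit <- attr(p_n, "fit")
  expect_equal(as.integer(p_n), fit$power[which.max(fit$r2)])

  # constant genes are dropped with a warning before correlation
  expr2 <- rbind(expr, const = rep(1, 30))
  msgs <- capture_warnings(pick_soft_threshold(expr2, 1:4))
  expect_true(any(grepl("constant", msgs)))
})

test_that("eigengenes summarize modules and obey the sign convention", {
  set.seed(5)
  prof <- rnorm(30)
  expr <- matrix(rep(2 * prof + 1, 6), nrow = 6, byrow = TRUE,
                 dimnames = list(paste0("g", 1:6), paste0("s", 1:30)))
  part <- setNames(rep(1L, 6), rownames(expr))
  eig <- module_eigengenes(expr, part)
  e <- eig$me["ME1", ]
  expect_equal(eig$var_explained[["ME1"]], 1)
  expect_equal(abs(cor(e, prof)), 1)
  expect_gte(cor(e, colMeans(expr)), 0)
  expect_equal(sum(e^2), 1)  # unit norm

  # flipping every member gene flips the eigengene, var explained unchanged
  eig_f <- module_eigengenes(-expr, part)
  expect_equal(eig_f$me["ME1", ], -e)
  expect_equal(eig_f$var_explained, eig$var_explained)

  # permuting samples permutes the eigengene identically
  perm <- sample(30)
  eig_p <- module_eigengenes(expr[, perm], part)
  expect_equal(unname(eig_p$me["ME1", ]), unname(e[perm]))

  # duplicating member genes leaves it unchanged
  expr_d <- rbind(expr, `rownames<-`(expr, paste0("h", 1:6)))
  part_d <- setNames(rep(1L, 12), rownames(expr_d))
  expect_equal(module_eigengenes(expr_d, part_d)$me["ME1", ], e)

  # planted factor recovered
  co <- generate_cohort(sim_config(loading = 0.9, seed = 19L))
  eig2 <- module_eigengenes(co$expr, co$truth$modules)
  expect_gte(abs(cor(eig2$me["ME1", ], co$factors[1, ])), 0.95)

  # zero-variance members dropped with warning
  expr_z <- rbind(expr, z = rep(3, 30))
  part_z <- setNames(rep(1L, 7), rownames(expr_z))
  expect_warning(module_eigengenes(expr_z, part_z), "zero-variance")
})

test_that("module-trait correlations match cor.test pairwise-complete", {
  set.seed(6)
  n <- 10
  me <- matrix(rnorm(2 * n), 2,
               dimnames = list(c("ME1", "ME2"), paste0("s", 1:n)))
  traits <- data.frame(sample_id = paste0("s", 1:n),
                       tumor = rbinom(n, 1, 0.5),
                       HER2 = c(rbinom(n - 2, 1, 0.5), NA, NA))
  mt <- module_trait_cor(me, traits)
  for (i in seq_len(nrow(mt))) {
    e <- me[mt$module[i], ]
    tr <- traits[[mt$trait[i]]]
    ok <- !is.na(tr)
    ct <- cor.test(e[ok], tr[ok])
    expect_equal(mt$r[i], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(mt$p[i], ct$p.value, tolerance = 1e-12)
    expect_equal(mt$n[i], sum(ok))
  }

  # eigengene equal to the (standardized) trait: r = 1
  me1 <- matrix(scale(traits$tumor)[, 1], 1,
                dimnames = list("ME1", paste0("s", 1:n)))
  mt1 <- module_trait_cor(me1, traits[, c("sample_id", "tumor")])
  expect_equal(mt1$r, 1)

  # orthogonal eigengene: r = 0, p = 1
  me0 <- matrix(rep(c(1, -1), 5), 1,
                dimnames = list("ME1", paste0("s", 1:n)))
  tr0 <- data.frame(sample_id = paste0("s", 1:n),
                    tumor = c(1, 1, 0, 0, 1, 1, 0, 0, 1, 1))
  mt0 <- module_trait_cor(me0, tr0)
  expect_equal(mt0$r, 0)
  expect_equal(mt0$p, 1)
  expect_false(mt0$significant)

  # constant trait: undefined, reported missing with warning
  trc <- data.frame(sample_id = paste0("s", 1:n), tumor = rep(1, n))
  msgs <- capture_warnings(mtc <- module_trait_cor(me, trc))
  expect_true(any(grepl("constant", msgs)))
  expect_true(all(is.na(mtc$r)))
})
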