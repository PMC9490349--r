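test_that("describe_distribution reproduces published descriptive statistics", {
  h <- table1_hammers()
  len <- describe_distribution(h$max_length_mm)
  expect_equal(round(len$mean, 1), 224.4)
  vol <- describe_distribution(h$volume_cm3)
  expect_equal(vol$mean, 2726, tolerance = 0.05 / 2726)
  expect_equal(vol$sd, 2208.26, tolerance = 0.01 / 2208.26)
  # oracle: two-pass mean/variance on seeded uniforms
  set.seed(101)
  x <- runif(1000)
  d <- describe_distribution(x)
  mu <- sum(x) / 1000
  expect_equal(d$mean, mu, tolerance = 1e-12)
  expect_equal(d$sd, sqrt(sum((x - mu)^2) / 999), tolerance = 1e-12)
  expect_equal(d$min, min(x))
  expect_equal(d$max, max(x))
})

test_that("describe_distribution edge cases and data-frame interface", {
  expect_error(describe_distribution(numeric(0)), class = "percussr_parameter")
  one <- describe_distribution(5)
  expect_true(is.na(one$sd))
  const <- describe_distribution(c(5, 5, 5))
  expect_equal(unlist(const[c("min", "max", "mean", "sd")]),
               c(min = 5, max = 5, mean = 5, sd = 0))
  h <- load_djouroutou_tables()
  by_type <- describe_distribution(h, max_length_mm, by = tool_type)
  expect_equal(nrow(by_type), 2)
  anv <- by_type[by_type$group == "anvil", ]
  expect_equal(anv$mean, 643.85, tolerance = 0.01 / 643.85)
})

test_that("Mann-Whitney U: statistic convention and exact enumeration", {
  t1 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(t1$statistic), 0)
  expect_true(t1$exact)
  expect_equal(t1$p.value, 0.1, tolerance = 1e-12) # 2 / C(6,3) extremes

  t2 <- mann_whitney_u(c(1, 4), c(2, 3))
  expect_equal(unname(t2$statistic), 2) # n1 n2 / 2: perfect interleaving
  expect_equal(t2$u1 + t2$u2, 4)

  # exact p equals the pwilcox null-distribution oracle for seeded samples
  set.seed(55)
  for (trial in 1:20) {
    a <- rnorm(6)
    b <- rnorm(6)
    tt <- mann_whitney_u(a, b)
    expect_true(tt$exact)
    expect_equal(tt$p.value, mwu_exact_p_oracle(tt$u1, 6, 6),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney U: symmetry, ties path, errors", {
  set.seed(56)
  a <- rnorm(8)
  b <- rnorm(15)
  t_ab <- mann_whitney_u(a, b)
  t_ba <- mann_whitney_u(b, a)
  expect_equal(t_ab$statistic, t_ba$statistic)
  expect_equal(t_ab$p.value, t_ba$p.value)
  expect_false(t_ab$exact) # N > 12: normal approximation
  # tie-corrected approximation agrees with wilcox.test's
  x <- c(1, 2, 2, 3, 5, 7, 7, 7)
  y <- c(2, 4, 4, 6, 6, 8, 9, 10)
  tt <- mann_whitney_u(x, y)
  wt <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE,
                                            exact = FALSE))
  expect_equal(tt$p.value, wt$p.value, tolerance = 1e-9)
  expect_error(mann_whitney_u(numeric(0), y), class = "percussr_parameter")
  # identical samples: U at its midpoint, p = 1
  ti <- mann_whitney_u(c(1, 2, 3, 9), c(1, 2, 3, 9))
  expect_equal(unname(ti$statistic), 8)
  expect_equal(ti$p.value, 1)
})

test_that("Kruskal-Wallis reproduces published H statistics exactly", {
  h <- table1_hammers()
  kw_len <- kruskal_wallis(h$max_length_mm, h$raw_material)
  expect_equal(unname(kw_len$statistic), 1.641, tolerance = 1e-3 / 1.641)
  expect_equal(kw_len$df, 2L)
  kw_wid <- kruskal_wallis(h$max_breadth_mm, h$raw_material)
  expect_equal(unname(kw_wid$statistic), 1.664, tolerance = 1e-3 / 1.664)
  kw_thk <- kruskal_wallis(h$max_thickness_mm, h$raw_material)
  expect_equal(unname(kw_thk$statistic), 0.618, tolerance = 1e-3 / 0.618)
  kw_vol <- kruskal_wallis(h$volume_cm3, h$nut_species)
  expect_equal(unname(kw_vol$statistic), 6.060, tolerance = 1.1e-3 / 6.060)
  kw_mas <- kruskal_wallis(h$mass_g, h$nut_species)
  expect_equal(kw_mas$statistic, kw_vol$statistic, tolerance = 1e-12)
})

test_that("Kruskal-Wallis: symmetry zero, oracle p, agreement with kruskal.test", {
  kw0 <- kruskal_wallis(list(c(1, 6), c(2, 5), c(3, 4)))
  expect_equal(unname(kw0$statistic), 0, tolerance = 1e-12)

  set.seed(57)
  x <- rnorm(30)
  g <- rep(c("a", "b", "c"), 10)
  kw <- kruskal_wallis(x, g)
  ref <- stats::kruskal.test(x, factor(g))
  expect_equal(unname(kw$statistic), unname(ref$statistic), tolerance = 1e-12)
  expect_equal(kw$p.value, ref$p.value, tolerance = 1e-12)
  # chi-squared upper tail by numerical quadrature of the density
  H <- unname(kw$statistic)
  q <- stats::integrate(function(t) stats::dchisq(t, 2), H, Inf,
                        rel.tol = 1e-12)$value
  expect_equal(kw$p.value, q, tolerance = 1e-8)

  expect_error(kruskal_wallis(list(c(1, 2, 3))), class = "percussr_parameter")
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))),
               class = "percussr_degenerate")
})

test_that("KW with two groups matches the squared MWU z in the no-ties limit", {
  set.seed(58)
  a <- rnorm(30)
  b <- rnorm(30, 0.5)
  kw <- kruskal_wallis(list(a = a, b = b))
  mw <- mann_whitney_u(a, b, exact = FALSE)
  # without continuity correction z^2 = H exactly in the absence of ties
  u1 <- mw$u1
  sigma2 <- 30 * 30 * 61 / 12
  z <- (u1 - 450) / sqrt(sigma2)
  expect_equal(unname(kw$statistic), z^2, tolerance = 1e-6)
})

test_that("Dunn's post hoc: Bonferroni arithmetic and formula oracle", {
  # p_adj = min(1, m p): 0.02 -> 0.06 with m = 3; 0.5 -> 1
  expect_equal(stats::p.adjust(c(0.02, 0.5, 0.5), "bonferroni")[1], 0.06)
  expect_equal(stats::p.adjust(c(0.5, 0.5, 0.5), "bonferroni")[1], 1)

  set.seed(59)
  x <- c(rnorm(7), rnorm(8, 1), rnorm(6, 2))
  g <- rep(c("a", "b", "c"), c(7, 8, 6))
  d <- dunn_posthoc(x, g)
  expect_equal(nrow(d), 3)
  expect_equal(d$p.adj, pmin(1, 3 * d$p.value))
  # independent recomputation with its own ranking code
  N <- length(x)
  r <- (order(order(x))) # ranks without ties (continuous draws)
  for (row in seq_len(nrow(d))) {
    gi <- d$group1[row]; gj <- d$group2[row]
    ri <- mean(r[g == gi]); rj <- mean(r[g == gj])
    se <- sqrt((N * (N + 1) / 12) * (1 / sum(g == gi) + 1 / sum(g == gj)))
    expect_equal(d$z[row], (ri - rj) / se, tolerance = 1e-12)
  }
  expect_error(dunn_posthoc(x[g != "c"], g[g != "c"]),
               class = "percussr_parameter")
})

test_that("PCA: variance bookkeeping, sign convention, eigen oracle", {
  set.seed(60)
  base <- rnorm(40)
  perfect <- tibble::tibble(v1 = base, v2 = 3 * base + 2)
  p <- run_pca(perfect)
  expect_equal(p$percent_variance[1], 100, tolerance = 1e-9)

  tab <- tibble::as_tibble(matrix(rnorm(100), 20, 5,
                                  dimnames = list(NULL, paste0("v", 1:5))))
  p2 <- run_pca(tab)
  expect_equal(sum(p2$percent_variance), 100, tolerance = 1e-6)
  expect_equal(unname(crossprod(p2$loadings)), diag(5), tolerance = 1e-9)
  for (j in 1:5) expect_gt(p2$loadings[which.max(abs(p2$loadings[, j])), j], 0)
  # eigenvalues of the explicitly formed correlation matrix
  ev <- eigen(stats::cor(as.matrix(tab)), symmetric = TRUE)$values
  expect_equal(p2$sdev^2, ev, tolerance = 1e-9)

  bad <- tab
  bad$v3 <- 1
  expect_error(run_pca(bad), "v3", class = "percussr_degenerate")
})

test_that("compare_assemblages: identical tables, schema errors, empties", {
  asm <- generate_assemblage(12, 12, seed = 4)
  w <- asm$wear
  cmp <- suppressMessages(compare_assemblages(w, w))
  expect_true(all(cmp$tests$p.value > 0.99))
  expect_false(any(cmp$tests$significant))
  expect_equal(nrow(cmp$tests), 9)

  broken <- w[, setdiff(names(w), "pa_percent")]
  expect_error(suppressMessages(compare_assemblages(broken, w)),
               "pa_percent", class = "percussr_schema")
  expect_error(compare_assemblages(w[0, ], w), class = "percussr_parameter")
})

test_that("tidy and glance methods return well-formed tibbles", {
  tt <- mann_whitney_u(rnorm(5), rnorm(5))
  td <- tidy(tt)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$statistic_name, "U")
  kw <- kruskal_wallis(list(rnorm(5), rnorm(5), rnorm(5)))
  expect_equal(tidy(kw)$df, 2L)
  p <- run_pca(tibble::as_tibble(matrix(rnorm(60), 15, 4,
                                        dimnames = list(NULL, paste0("v", 1:4)))))
  expect_equal(nrow(tidy(p)), 16)
  expect_equal(nrow(glance(p)), 4)
  expect_equal(glance(p)$cumulative_percent[4], 100, tolerance = 1e-9)
})
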