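# Synthetic cohort generator: node geometry, the latent-factor model and its
# analytic correlation oracle, and cohort reproducibility.

test_that("default node table mirrors the 110-region bilateral parcellation", {
  tab <- make_node_table(generator_config())
  expect_equal(nrow(tab), 110L)
  expect_equal(tab$node_id, 0:109)
  expect_equal(sum(tab$hemisphere == "L"), 55L)
  expect_equal(sum(tab$hemisphere == "R"), 55L)
  # 48 cortical + 7 subcortical names per hemisphere.
  for (h in c("L", "R")) {
    nm <- tab$name[tab$hemisphere == h]
    expect_equal(sum(grepl("^cortical_", nm)), 48L)
    expect_setequal(sub("_[LR]$", "", nm[!grepl("^cortical_", nm)]),
                    c("thalamus", "caudate", "putamen", "pallidum",
                      "amygdala", "accumbens", "hippocampus"))
  }
  expect_true("caudate_R" %in% tab$name)
  expect_true(all(is.finite(as.matrix(tab[, c("x_mm", "y_mm", "z_mm")]))))
})

test_that("node pairs are mirrored in x and share module and flags", {
  tab <- make_node_table(generator_config(n_nodes = 4L, n_modules = 2L))
  expect_equal(nrow(tab), 4L)
  left <- tab[tab$hemisphere == "L", ]
  right <- tab[tab$hemisphere == "R", ]
  expect_equal(left$x_mm, -right$x_mm)
  expect_equal(left$y_mm, right$y_mm)
  expect_equal(left$z_mm, right$z_mm)
  expect_equal(left$module_id, right$module_id)
  expect_equal(left$longrange_flag, right$longrange_flag)
})

test_that("node table construction is deterministic and validates its inputs", {
  cfg <- generator_config()
  expect_identical(make_node_table(cfg), make_node_table(cfg))
  expect_error(generator_config(n_nodes = 109L), "even")
  expect_error(generator_config(n_nodes = 10L, n_modules = 6L), "n_modules")
  expect_error(generator_config(noise_sd = 0), "noise_sd")
  expect_error(generator_config(temporal_smoothing = 1), "temporal_smoothing")
})

test_that("long-range flags cover the requested fraction across several distant modules", {
  tab <- make_node_table(generator_config())
  expect_equal(sum(tab$longrange_flag), 16L)  # round(0.15 * 110 / 2) pairs
  expect_gte(length(unique(tab$module_id[tab$longrange_flag])), 2L)
  # Flagged nodes should be mutually farther apart than typical node pairs.
  xyz <- as.matrix(tab[, c("x_mm", "y_mm", "z_mm")])
  d <- as.matrix(dist(xyz))
  fl <- which(tab$longrange_flag)
  expect_gt(mean(d[fl, fl][upper.tri(d[fl, fl])]), mean(d[upper.tri(d)]))
})

test_that("subject simulation respects group labels, shape and determinism", {
  cfg <- small_config()
  tab <- make_node_table(cfg)
  rec <- simulate_subject(cfg, tab, "case", seed = 3L)
  expect_s3_class(rec, "subject_record")
  expect_equal(dim(rec$series), c(cfg$n_nodes, cfg$n_volumes))
  expect_true(all(is.finite(rec$series)))
  rec2 <- simulate_subject(cfg, tab, "case", seed = 3L)
  expect_identical(rec$series, rec2$series)
  expect_error(simulate_subject(cfg, tab, "patient", seed = 3L), "unknown group")
})

test_that("uncoupled nodes are independent and fully coupled nodes correlate to 1", {
  cfg <- small_config(n_volumes = 4000L,
                      global_coupling_control = 0, module_coupling = 0,
                      longrange_coupling_control = 0, longrange_node_fraction = 0)
  tab <- make_node_table(cfg)
  rec <- simulate_subject(cfg, tab, "control", seed = 8L)
  cm <- cor(t(rec$series))
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.08)

  # Near-zero noise, shared module signal only: same-module correlation -> 1.
  cfg2 <- small_config(noise_sd = 1e-8, global_coupling_control = 0,
                       longrange_coupling_control = 0, longrange_node_fraction = 0)
  tab2 <- make_node_table(cfg2)
  rec2 <- simulate_subject(cfg2, tab2, "control", seed = 8L)
  same_mod <- which(tab2$module_id == tab2$module_id[1L])
  cm2 <- cor(t(rec2$series[same_mod, ]))
  expect_equal(min(cm2), 1, tolerance = 1e-6)
})

test_that("expected_correlation gives the closed-form latent-factor values", {
  cfg <- small_config(global_coupling_control = 1, module_coupling = 1,
                      longrange_coupling_control = 0, noise_sd = 1,
                      longrange_node_fraction = 0)
  tab <- make_node_table(cfg)
  dm <- tab$node_id[tab$module_id != tab$module_id[1L]][1L]
  # g=1, w=1, b=0, noise 1, different modules: g^2 / (g^2 + w^2 + s^2) = 1/3.
  expect_equal(expected_correlation(cfg, tab, 0L, dm, "control"), 1 / 3)
  sm <- tab$node_id[tab$module_id == tab$module_id[1L] & tab$node_id != 0L][1L]
  expect_equal(expected_correlation(cfg, tab, 0L, sm, "control"), 2 / 3)
  expect_error(expected_correlation(cfg, tab, 3L, 3L, "control"), "i == j")

  cfg0 <- small_config(global_coupling_control = 0, module_coupling = 0,
                       longrange_coupling_control = 0)
  tab0 <- make_node_table(cfg0)
  expect_equal(expected_correlation(cfg0, tab0, 0L, 1L, "control"), 0)
})

test_that("analytic oracle matches Monte-Carlo correlations at large T", {
  # Two parameter sets with couplings <= 2, including long-range flags.
  cfgs <- list(
    generator_config(n_nodes = 6L, n_modules = 3L, n_volumes = 1e5,
                     global_coupling_control = 0.5, module_coupling = 1,
                     longrange_coupling_control = 0.8,
                     longrange_node_fraction = 0.34, random_seed = 21L),
    generator_config(n_nodes = 6L, n_modules = 2L, n_volumes = 1e5,
                     global_coupling_case = 2, module_coupling = 0.4,
                     longrange_coupling_case = 1.5, temporal_smoothing = 0.6,
                     longrange_node_fraction = 0.5, random_seed = 22L)
  )
  groups <- c("control", "case")
  for (s in seq_along(cfgs)) {
    cfg <- cfgs[[s]]
    tab <- make_node_table(cfg)
    emp <- expected_correlation_empirical(cfg, tab, groups[s],
                                          n_volumes = 1e5, seed = 30L + s,
                                          remove_global = FALSE)
    for (i in 0:(cfg$n_nodes - 2L)) for (j in (i + 1L):(cfg$n_nodes - 1L)) {
      expect_lt(abs(emp[i + 1L, j + 1L] -
                      expected_correlation(cfg, tab, i, j, groups[s])), 0.01)
    }
  }
})

test_that("raising case global coupling raises the expected mean correlation monotonically", {
  grid <- c(0.2, 0.6, 1.0)
  means <- vapply(grid, function(g) {
    cfg <- small_config(global_coupling_case = g)
    tab <- make_node_table(cfg)
    pairs <- t(combn(tab$node_id, 2))
    mean(apply(pairs, 1L, function(p) {
      expected_correlation(cfg, tab, p[1L], p[2L], "case")
    }))
  }, 0)
  expect_true(all(diff(means) > 0))

  # Empirical check (pre-removal) on the same 3-point grid.
  emp_means <- vapply(grid, function(g) {
    cfg <- small_config(global_coupling_case = g, n_volumes = 5000L)
    tab <- make_node_table(cfg)
    rec <- simulate_subject(cfg, tab, "case", seed = 77L)
    cm <- cor(t(rec$series))
    mean(cm[upper.tri(cm)])
  }, 0)
  expect_true(all(diff(emp_means) > 0))
})

test_that("cohorts have the configured composition and are reproducible", {
  cfg <- generator_config(n_volumes = 16L)  # short series: composition only
  co <- simulate_cohort(cfg)
  groups <- vapply(co$subjects, function(s) s$group, "")
  expect_length(co$subjects, 30L)
  expect_equal(sum(groups == "control"), 16L)
  expect_equal(sum(groups == "case"), 14L)

  cfg2 <- small_config()
  co1 <- simulate_cohort(cfg2)
  co2 <- simulate_cohort(cfg2)
  expect_identical(lapply(co1$subjects, `[[`, "series"),
                   lapply(co2$subjects, `[[`, "series"))

  co0 <- simulate_cohort(small_config(n_controls = 0L))
  expect_true(all(vapply(co0$subjects, function(s) s$group, "") == "case"))
})
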