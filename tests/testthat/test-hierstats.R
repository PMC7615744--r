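make_nested <- function(values_by_animal, groups) {
  rows <- lapply(names(values_by_animal), function(a) {
    v <- values_by_animal[[a]]
    data.frame(value = v,
               cell_id = paste0(a, "_c", seq_along(v)),
               animal_id = a, group = groups[[a]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("dataset validation enforces the nesting contract", {
  d <- make_nested(list(a1 = 1:3, a2 = 2:4, b1 = 1:3, b2 = 2:4),
                   c(a1 = "g1", a2 = "g1", b1 = "g2", b2 = "g2"))
  expect_s3_class(hierarchical_dataset(d), "hierarchical_dataset")
  bad <- d; bad$animal_id[1] <- "a2"  # cell duplicated across animals
  bad <- rbind(bad, d[1, ])
  expect_error(hierarchical_dataset(bad), "more than one animal")
  one_group <- d; one_group$group <- "g1"
  expect_error(hierarchical_dataset(one_group), "two groups")
  expect_error(hierarchical_dataset(d[, -1]), "missing columns")
})

test_that("identical groups give zero effect and p = 1 under the degenerate convention", {
  d <- make_nested(list(a1 = c(5, 5), a2 = c(5, 5), b1 = c(5, 5), b2 = c(5, 5)),
                   c(a1 = "g1", a2 = "g1", b1 = "g2", b2 = "g2"))
  res <- animal_mean_test(d)
  expect_equal(res$effect, 0)
  expect_equal(res$p_value, 1)
})

test_that("animal means make the test invariant to duplicating cells within an animal", {
  d <- make_nested(list(a1 = c(1, 2, 4), a2 = c(2, 3), a3 = c(5, 4),
                        b1 = c(4, 6), b2 = c(5, 7, 9), b3 = c(6, 6)),
                   c(a1 = "g1", a2 = "g1", a3 = "g1",
                     b1 = "g2", b2 = "g2", b3 = "g2"))
  res1 <- animal_mean_test(d)
  dup <- rbind(d, transform(d, cell_id = paste0(cell_id, "_dup")))
  res2 <- animal_mean_test(dup)
  expect_equal(res2$effect, res1$effect)
  expect_equal(res2$p_value, res1$p_value)
})

test_that("swapping group labels negates the effect and preserves the p-value", {
  d <- make_nested(list(a1 = c(1, 2), a2 = c(2, 3), b1 = c(4, 6), b2 = c(5, 7)),
                   c(a1 = "g1", a2 = "g1", b1 = "g2", b2 = "g2"))
  res <- animal_mean_test(d)
  swapped <- d
  swapped$group <- ifelse(d$group == "g1", "g2", "g1")
  res_s <- animal_mean_test(swapped)
  expect_equal(res_s$effect, -res$effect)
  expect_equal(res_s$p_value, res$p_value)
})

test_that("insufficient replication is a structured error", {
  d <- make_nested(list(a1 = c(1, 2), b1 = c(4, 6), b2 = c(5, 7)),
                   c(a1 = "g1", b1 = "g2", b2 = "g2"))
  expect_error(animal_mean_test(d),
               class = "caflux_insufficient_replication")
})

test_that("the hierarchical bootstrap is seeded, consistent and warns at low n_boot", {
  d <- make_nested(list(a1 = c(1, 2, 4), a2 = c(2, 3), a3 = c(1, 5),
                        b1 = c(4, 6), b2 = c(5, 7, 9), b3 = c(3, 6)),
                   c(a1 = "g1", a2 = "g1", a3 = "g1",
                     b1 = "g2", b2 = "g2", b3 = "g2"))
  b1 <- hierarchical_bootstrap(d, n_boot = 500, seed = 3)
  b2 <- hierarchical_bootstrap(d, n_boot = 500, seed = 3)
  expect_identical(b1$ci95, b2$ci95)
  expect_identical(b1$p_value, b2$p_value)
  expect_true(b1$ci95[1] <= b1$effect && b1$effect <= b1$ci95[2])
  # same point effect as the animal-mean route
  expect_equal(b1$effect, animal_mean_test(d)$effect)
  expect_warning(hierarchical_bootstrap(d, n_boot = 100, seed = 1),
                 "n_boot")
})

test_that("the bootstrap detects a two-animal-s.d. group shift most of the time", {
  n_detect <- 0L
  n_reps <- 30L
  for (r in seq_len(n_reps)) {
    sp <- cohort_spec(n_animals_per_group = 6, cells_per_animal = 10,
                      animal_sd = 0.1, cell_sd = 0.2,
                      group_effects = list(k_serca = 1.2),  # 2x animal s.d.
                      seed = 5000 + r)
    cells <- make_cohort(sp, traces = FALSE)$cells
    d <- data.frame(value = cells$k_serca, cell_id = cells$cell_id,
                    animal_id = cells$animal_id, group = cells$group)
    ci <- hierarchical_bootstrap(d, n_boot = 400, seed = r)$ci95
    n_detect <- n_detect + (ci[1] > 0 || ci[2] < 0)
  }
  expect_gte(n_detect / n_reps, 0.75)
})

test_that("null p-values from the animal-mean test are approximately uniform", {
  pvals <- vapply(1:300, function(r) {
    sp <- cohort_spec(n_animals_per_group = 7, cells_per_animal = 15,
                      animal_sd = 0.1, cell_sd = 0.2, seed = 70000 + r)
    cells <- make_cohort(sp, traces = FALSE)$cells
    animal_mean_test(data.frame(value = cells$k_serca,
                                cell_id = cells$cell_id,
                                animal_id = cells$animal_id,
                                group = cells$group))$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the pseudo-replication demo shows naive inflation growing with animal variance", {
  base <- myocyte_params()
  rates <- lapply(c(0, 0.08, 0.2), function(asd) {
    sp <- cohort_spec(n_animals_per_group = 6, cells_per_animal = 20,
                      animal_sd = asd, cell_sd = 0.2, seed = 811)
    naive_vs_hierarchical_demo(sp, base, n_reps = 300)
  })
  naive <- vapply(rates, function(t) t$rejection_rate[1], numeric(1))
  hier <- vapply(rates, function(t) t$rejection_rate[2], numeric(1))
  # with no animal variance both are near the nominal level
  expect_lt(abs(naive[1] - 0.05), 0.035)
  expect_lt(abs(hier[1] - 0.05), 0.035)
  # naive inflation is monotone in the between-animal s.d. and large at the top
  expect_true(all(diff(naive) > 0))
  expect_gt(naive[3], 0.2)
  expect_lt(abs(hier[3] - 0.05), 0.04)
  # a spec with group effects is rejected as a null harness
  sp_bad <- cohort_spec(group_effects = list(k_serca = 0.8))
  expect_error(naive_vs_hierarchical_demo(sp_bad), "null cohort")
})
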