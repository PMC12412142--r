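# SST verdict logic: summaries, threshold and bias criteria, protocols.

test_that("replicate summaries compute mean and n-1 standard deviation", {
  r <- clean_replicates(list(c(a = 1.0, b = 0.0), c(a = 1.0, b = 2.0)))
  s <- summarize_replicates(r)
  expect_equal(s$mean_error[s$compound == "a"], 1.0)
  expect_equal(s$sd_error[s$compound == "a"], 0.0)
  expect_equal(s$mean_error[s$compound == "b"], 1.0)
  expect_equal(s$sd_error[s$compound == "b"], sqrt(2), tolerance = 1e-10)

  # a compound absent from all replicates
  s2 <- summarize_replicates(r, compounds = c("a", "b", "ghost"))
  g <- s2[s2$compound == "ghost", ]
  expect_equal(g$n, 0L)
  expect_equal(g$n_missing, 2L)
  expect_true(is.na(g$mean_error))

  expect_error(summarize_replicates(list()), "no injection")
  expect_error(summarize_replicates(list(inj(c(a = 1)),
                                         inj(c(a = 1), polarity = "NEG"))),
               "mixed polarities")
})

test_that("threshold criterion distinguishes per-replicate and mean modes", {
  ok <- clean_replicates(list(c(a = 2.9), c(a = -2.9)))
  expect_length(check_threshold(ok, 3, "each"), 0L)

  mixed <- clean_replicates(list(c(a = 2.0), c(a = 3.5)))
  expect_equal(check_threshold(mixed, 3, "each"), "a")
  expect_length(check_threshold(mixed, 3, "mean"), 0L)  # mean 2.75

  zero <- clean_replicates(list(c(a = 0, b = 0), c(a = 0, b = 0)))
  expect_length(check_threshold(zero, 3), 0L)
})

test_that("the exact sign test matches brute-force enumeration", {
  # closed form for a unanimous panel of 13
  s <- summarize_replicates(clean_replicates(list(
    setNames(rep(0.4, 13), paste0("c", 1:13)),
    setNames(rep(0.6, 13), paste0("c", 1:13)))))
  b <- check_bias(s)
  expect_true(b$flag)
  expect_equal(b$sign, "+")
  expect_equal(b$p_value, 2 * 0.5^13)

  # the p-value formula equals enumeration for every n <= 13 and every k
  for (n in c(5, 8, 11, 13)) {
    for (k in 0:n) {
      p_pkg <- min(1, 2 * pbinom(max(k, n - k) - 1L, n, 0.5,
                                 lower.tail = FALSE))
      expect_equal(p_pkg, enum_sign_p(n, k),
                   label = sprintf("n=%d k=%d", n, k))
    }
  }
})

test_that("balanced signs and sparse panels never flag bias", {
  bal <- summarize_replicates(clean_replicates(list(
    setNames(c(1, 1, 1, 1, -1, -1, -1, -1), paste0("c", 1:8)))))
  b <- check_bias(bal)
  expect_false(b$flag)
  expect_equal(b$p_value, 1)

  sparse <- summarize_replicates(clean_replicates(list(
    c(a = 1, b = 1, c = 1))))
  expect_warning(b3 <- check_bias(sparse), "inconclusive")
  expect_false(b3$flag)
  expect_true(b3$inconclusive)
})

test_that("the two-injection outlier rule demands a third injection", {
  zero <- clean_replicates(list(balanced_errors(0), balanced_errors(0)))
  expect_equal(unclass(adaptive_protocol(zero))[1], "ACCEPT_TWO")

  gap <- clean_replicates(list(c(a = 0.2), c(a = 2.1)))  # gap 1.9 > 1.5
  out <- adaptive_protocol(gap)
  expect_equal(unclass(out)[1], "THIRD_INJECTION")
  expect_match(attr(out, "reasons"), "gap")

  big <- clean_replicates(list(c(a = 3.4), c(a = 0.1)))
  expect_equal(unclass(adaptive_protocol(big))[1], "THIRD_INJECTION")

  lonely <- clean_replicates(list(c(a = 1, b = 1), c(a = 1)))
  out2 <- adaptive_protocol(lonely)
  expect_equal(unclass(out2)[1], "THIRD_INJECTION")
  expect_match(attr(out2, "reasons"), "only one replicate")

  expect_error(adaptive_protocol(clean_replicates(list(c(a = 1)))),
               "exactly two")
})

test_that("evaluate_sst composes threshold, bias and detection criteria", {
  reps <- clean_replicates(replicate(5, balanced_errors(0.5) +
                                       rnorm(8, 0, 0.05), simplify = FALSE))
  v <- evaluate_sst(reps)
  expect_true(v$pass)
  expect_equal(v$recommendation, "PROCEED")

  # one replicate with one compound at 5 ppm fails and asks to recalibrate
  bad <- reps
  bad[[3]]$errors[["Caffeine"]] <- 5
  v2 <- evaluate_sst(bad)
  expect_false(v2$pass)
  expect_equal(v2$failed_compounds, "Caffeine")
  expect_equal(v2$recommendation, "RECALIBRATE")

  # two clean replicates with a wide within-pair gap: third injection
  e1 <- balanced_errors(0.1); e2 <- balanced_errors(0.1)
  e2[["Caffeine"]] <- e1[["Caffeine"]] + 1.9
  v3 <- evaluate_sst(clean_replicates(list(e1, e2)))
  expect_true(v3$pass)
  expect_equal(v3$recommendation, "THIRD_INJECTION")

  # a compound undetected in every replicate fails the SST
  gone <- lapply(reps, function(r) {
    r$errors <- r$errors[names(r$errors) != "Verapamil"]; r
  })
  v4 <- evaluate_sst(gone)
  expect_false(v4$pass)
  expect_equal(v4$missing_compounds, "Verapamil")
  # unless explicitly allowlisted
  v5 <- evaluate_sst(gone, config = sst_config(allow_missing = "Verapamil"))
  expect_true(v5$pass)

  expect_error(evaluate_sst(reps[1]), "2-5")
  expect_error(evaluate_sst(list(inj(balanced_errors(), phase = "PRE"),
                                 inj(balanced_errors(), phase = "POST"))),
               "mixed phases")
})

test_that("the verdict is invariant under replicate and compound order", {
  set.seed(21)
  reps <- clean_replicates(replicate(4, balanced_errors(0.8) +
                                       rnorm(8, 0, 0.3), simplify = FALSE))
  v1 <- evaluate_sst(reps)
  shuffled <- lapply(rev(reps), function(r) {
    r$errors <- r$errors[sample(names(r$errors))]; r
  })
  v2 <- evaluate_sst(shuffled)
  expect_equal(v1$pass, v2$pass)
  expect_equal(v1$recommendation, v2$recommendation)
  expect_equal(v1$failed_compounds, v2$failed_compounds)
  expect_equal(v1$bias$p_value, v2$bias$p_value)
})

test_that("shrinking all errors toward zero never turns a pass into a recalibration", {
  set.seed(33)
  tested <- 0L
  for (i in 1:20) {
    reps <- clean_replicates(replicate(
      5, setNames(rnorm(8, 0, 1.0), pos_compounds()), simplify = FALSE))
    v_full <- evaluate_sst(reps)
    if (v_full$recommendation != "PROCEED") next
    tested <- tested + 1L
    for (lambda in c(0.5, 0.1, 0)) {
      shrunk <- lapply(reps, function(r) { r$errors <- r$errors * lambda; r })
      expect_equal(evaluate_sst(shrunk)$recommendation, "PROCEED",
                   label = sprintf("case %d, lambda %.1f", i, lambda))
    }
  }
  expect_gt(tested, 0L)
})

test_that("verdicts serialise to JSON and Markdown", {
  reps <- clean_replicates(replicate(3, balanced_errors(0.4),
                                     simplify = FALSE))
  v <- evaluate_sst(reps)
  j <- jsonlite::fromJSON(verdict_json(v))
  expect_true(j$pass)
  expect_equal(j$recommendation, "PROCEED")
  expect_equal(nrow(j$summaries), 8L)
  md <- verdict_markdown(v)
  expect_match(md, "\\| Compound \\|")
  expect_match(md, "PASS")
})
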