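test_that("built-in rulesets transcribe the threshold tables", {
  a2 <- builtin_ruleset("A2")
  expect_equal(length(a2$rules), 5)
  expect_true(all(vapply(a2$rules, function(r) length(r$conditions),
                         integer(1)) == 1))
  hyp <- a2$rules[[1]]$conditions[[1]]
  expect_equal(hyp$signal, "SPO2")
  expect_equal(hyp$op, "lt")
  expect_equal(hyp$value, 92)

  a3 <- builtin_ruleset("A3")
  expect_equal(length(a3$rules), 4)
  expect_equal(sum(vapply(a3$rules, function(r) length(r$conditions),
                          integer(1)) == 2), 3)

  a1 <- builtin_ruleset("A1")
  expect_equal(length(a1$rules), 10)
  r6 <- a1$rules[[which(vapply(a1$rules, `[[`, character(1),
                               "rule_id") == "A1-06")]]
  bounds <- lapply(r6$conditions, function(c) c(c$lower, c$upper))
  names(bounds) <- vapply(r6$conditions, `[[`, character(1), "signal")
  expect_equal(bounds$RR, c(9, 11))
  expect_equal(bounds$SPO2, c(92, 93))
  expect_equal(bounds$PR, c(111, 130))

  expect_error(builtin_ruleset("A9"))
})

test_that("strict and inclusive boundaries behave exactly as written", {
  streams <- list(SPO2 = make_stream(c(0, 1), c(91, 92)))
  rule_lt <- alarm_rule("hypoxia", vital_condition("SPO2", "lt", 92))
  trg <- evaluate_rule(rule_lt, streams)
  expect_equal(as.numeric(trg), as.numeric(T0))

  rule_le <- alarm_rule("le91", vital_condition("SPO2", "le", 91))
  expect_equal(length(evaluate_rule(rule_le, streams)), 1)
  streams2 <- list(SPO2 = make_stream(0, 91.99))
  expect_equal(length(evaluate_rule(rule_lt, streams2)), 1)
  expect_equal(length(evaluate_rule(rule_le, streams2)), 0)
})

test_that("combination rules require breaches within the overlap window", {
  rule <- builtin_ruleset("A3")$rules[[2]]  # RR > 25 & SpO2 < 90
  rr <- make_stream(10, 26)
  in_win <- list(RR = rr, SPO2 = make_stream(10 + 25 / 60, 89))
  out_win <- list(RR = rr, SPO2 = make_stream(10 + 35 / 60, 89))
  expect_equal(length(evaluate_rule(rule, in_win)), 1)
  expect_equal(length(evaluate_rule(rule, out_win)), 0)

  # missing or empty partner stream: the rule can never fire
  expect_equal(length(evaluate_rule(rule, list(RR = rr))), 0)
  empty <- list(RR = rr[0, ], SPO2 = rr[0, ])
  expect_equal(length(evaluate_rule(rule, empty)), 0)
})

test_that("a ruleset run produces per-rule logs and their union", {
  pr <- make_stream(c(0, 1, 2), c(55, 55, 55))
  streams <- list(PR = pr,
                  RR = make_stream(c(0, 1, 2), c(15, 15, 15)),
                  SPO2 = make_stream(c(0, 1, 2), c(96, 96, 96)))
  log2 <- run_ruleset(builtin_ruleset("A2"), streams)
  expect_equal(length(log2$by_rule[["A2-03"]]), 3)  # PR < 60 at every obs
  other <- setdiff(names(log2$by_rule), "A2-03")
  expect_true(all(vapply(log2$by_rule[other], length, integer(1)) == 0))
  expect_equal(as.numeric(log2$triggers), as.numeric(pr$timestamp))

  # PR 55 does not reach A3's PR < 45
  log3 <- run_ruleset(builtin_ruleset("A3"), streams)
  expect_equal(length(log3$triggers), 0)

  # breach-free streams are silent everywhere
  quiet <- list(PR = make_stream(0:5, rep(75, 6)),
                RR = make_stream(0:5, rep(16, 6)),
                SPO2 = make_stream(0:5, rep(97, 6)))
  logq <- run_ruleset(builtin_ruleset("A1"), quiet)
  expect_true(all(vapply(logq$by_rule, length, integer(1)) == 0))

  # duplicate timestamps across rules appear once in the union
  tachy <- list(PR = make_stream(c(0, 1), c(140, 140)),
                RR = make_stream(c(0, 1), c(26, 26)),
                SPO2 = make_stream(c(0, 1), c(85, 85)))
  loga <- run_ruleset(builtin_ruleset("A3"), tachy)
  expect_equal(length(loga$by_rule[["A3-01"]]), 2)
  expect_equal(length(loga$by_rule[["A3-02"]]), 2)
  expect_equal(length(loga$triggers), 2)
})

test_that("rule evaluation matches the brute-force pair scan", {
  set.seed(501)
  rules <- c(builtin_ruleset("A3")$rules, builtin_ruleset("A1")$rules[6:10],
             builtin_ruleset("A2")$rules)
  for (trial in 1:200) {
    streams <- list(
      PR = make_stream(sort(runif(15, 0, 10)), round(runif(15, 40, 140))),
      RR = make_stream(sort(runif(10, 0, 10)), round(runif(10, 5, 30))),
      SPO2 = make_stream(sort(runif(15, 0, 10)), round(runif(15, 85, 100)))
    )
    rule <- rules[[sample(length(rules), 1)]]
    fast <- as.numeric(evaluate_rule(rule, streams))
    slow <- brute_rule_triggers(rule, streams)
    expect_equal(fast, slow)
  }
})

test_that("lower thresholds trigger a subset of higher thresholds", {
  set.seed(502)
  for (trial in 1:50) {
    s <- list(SPO2 = make_stream(sort(runif(40, 0, 60)),
                                 round(runif(40, 85, 100), 1)))
    t91 <- evaluate_rule(alarm_rule("x", vital_condition("SPO2", "lt", 91)), s)
    t92 <- evaluate_rule(alarm_rule("x", vital_condition("SPO2", "lt", 92)), s)
    expect_true(all(as.numeric(t91) %in% as.numeric(t92)))
  }
})

test_that("combination triggers are contained in each condition's own triggers", {
  set.seed(503)
  for (trial in 1:50) {
    streams <- list(
      RR = make_stream(sort(runif(20, 0, 30)), round(runif(20, 10, 30))),
      SPO2 = make_stream(sort(runif(20, 0, 30)), round(runif(20, 85, 98)))
    )
    combo <- builtin_ruleset("A3")$rules[[2]]
    alone <- alarm_rule("rr", combo$conditions[[1]])
    t_combo <- as.numeric(evaluate_rule(combo, streams))
    t_alone <- as.numeric(evaluate_rule(alone, streams))
    expect_true(all(t_combo %in% t_alone))
  }
})

test_that("span overlap semantics are at least as strict as anchor semantics", {
  set.seed(504)
  rule <- builtin_ruleset("A1")$rules[[7]]  # three-signal combination
  for (trial in 1:30) {
    streams <- list(
      PR = make_stream(sort(runif(25, 0, 5)), round(runif(25, 85, 135))),
      RR = make_stream(sort(runif(25, 0, 5)), round(runif(25, 18, 26))),
      SPO2 = make_stream(sort(runif(25, 0, 5)), round(runif(25, 90, 97)))
    )
    t_anchor <- as.numeric(evaluate_rule(rule, streams, "anchor"))
    t_span <- as.numeric(evaluate_rule(rule, streams, "span"))
    expect_true(all(t_span %in% t_anchor))
  }
})
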