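# Macro validity and execution, plate scanning, session bookkeeping and
# the Welch mode comparison.

test_that("macro validity enforces the puncture-before-pulse interlock", {
  good <- InjectionMacro("ok", list(
    list(action = "await_puncture"), list(action = "pulse", pressure = 200)))
  expect_s4_class(good, "InjectionMacro")
  expect_error(InjectionMacro("bad", list(
    list(action = "pulse", pressure = 200))), "await_puncture")
  expect_error(InjectionMacro("bad2", list(
    list(action = "repeat", k = 0, steps = list(list(action = "retract"))))),
    "k >= 1")
  expect_error(InjectionMacro("bad3", list(list(action = "warp_drive"))),
               "unknown macro action")
})

test_that("macros round-trip through YAML and flatten repeats", {
  m <- defaultMacro("hindbrain")
  flat <- flattenMacroSteps(macroSteps(m))
  expect_identical(sum(vapply(flat, function(s) s$action == "pulse", TRUE)), 2L)
  tmp <- tempfile(fileext = ".yaml")
  macroToYaml(m, tmp)
  m2 <- macroFromYaml(tmp)
  expect_identical(macroSteps(m2), macroSteps(m))
})

test_that("macro execution follows step order and consumes detector events", {
  ctx <- list(touchdownEvent = list(kind = "touchdown", stepIndex = 6),
              punctureEvent = list(kind = "puncture", frameIndex = 11))
  res <- executeMacro(defaultMacro("doc"), ctx)
  expect_identical(res$outcome, "success")
  expect_identical(res$trace$action,
                   vapply(flattenMacroSteps(macroSteps(defaultMacro("doc"))),
                          function(s) s$action, character(1)))
  expect_true(all(diff(res$trace$t_start) > 0))
  expect_identical(res$pulsesDelivered, 1L)
  # a double-injection macro logs exactly two pulses
  res2 <- executeMacro(defaultMacro("hindbrain"), ctx)
  expect_identical(res2$pulsesDelivered, 2L)
  # missing puncture event: failure with reason, no exception
  res3 <- executeMacro(defaultMacro("doc"),
                       list(touchdownEvent = ctx$touchdownEvent))
  expect_identical(res3$outcome, "failure")
  expect_identical(res3$reason, "puncture_timeout")
  # empty macro: success with empty trace
  res4 <- executeMacro(InjectionMacro("noop", list()), ctx)
  expect_identical(res4$outcome, "success")
  expect_identical(nrow(res4$trace), 0L)
})

test_that("plate scanning orders larvae top-to-bottom then left-to-right", {
  p <- generatePlate(nLarvae = 6, imageSize = c(640, 640), seed = 17)
  dets <- scanPlate(plateImage(p))
  expect_length(dets, 6L)
  cy <- vapply(dets, function(d) d$centroid[2], numeric(1))
  expect_true(all(diff(cy) >= 0))
  # empty plate yields an empty list
  empty <- matrix(paintLevels()[["background"]], 400, 400)
  expect_length(scanPlate(empty), 0L)
  # equal-y tie is broken by x
  dets2 <- scanPlate(plateImage(p))
  ord <- order(cy, vapply(dets2, function(d) d$centroid[1], numeric(1)))
  expect_identical(ord, seq_along(dets2))
})

test_that("sessions log one row per larva and skip past the time budget", {
  p <- generatePlate(nLarvae = 6, imageSize = c(640, 640), seed = 23)
  rec <- runSession(p, defaultMacro("doc"), seed = 5)
  df <- sessionRecords(rec)
  expect_identical(nrow(df), 6L)
  expect_true(all(df$outcome %in% c("success", "failure", "skipped")))
  expect_true(all(df$t_end >= df$t_start))
  # a tight budget skips the tail of the plate
  recB <- runSession(p, defaultMacro("doc"), seed = 5, budgetSeconds = 60)
  dfB <- sessionRecords(recB)
  expect_identical(nrow(dfB), 6L)
  expect_gt(sum(dfB$outcome == "skipped"), 0L)
  expect_identical(sum(dfB$outcome == "skipped") +
                     sum(dfB$outcome != "skipped"), 6L)
  expect_true(all(dfB$reason[dfB$outcome == "skipped"] == "batch_time_budget"))
})

test_that("semi-automated sessions honour the scripted operator", {
  p <- generatePlate(nLarvae = 4, imageSize = c(560, 560), seed = 29)
  op <- function(larvaId, trace) if (larvaId == 3L) "abort" else "continue"
  rec <- runSession(p, defaultMacro("pvs"), mode = "semi_automated",
                    seed = 2, operator = op)
  df <- sessionRecords(rec)
  expect_identical(df$outcome[3], "failure")
  expect_identical(df$reason[3], "operator_abort")
  expect_identical(df$outcome[4], "success")
})

test_that("session summaries reproduce hand-counted statistics", {
  rec <- new("SessionRecord", records = data.frame(
    larva_id = 1:20, site = "doc_mid", mode = "automated",
    outcome = c(rep("success", 14), rep("failure", 6)),
    reason = NA_character_, t_start = (0:19) * 30, t_end = (1:20) * 30,
    survived = c(rep(TRUE, 10), rep(FALSE, 4), rep(NA, 6))),
    traces = list())
  s <- summarizeSession(rec)
  expect_identical(s@nInjected, 20L)
  expect_equal(s@successRate, 70)           # 14 of 20
  expect_equal(s@larvaePerHour, 120)        # 30 s per larva
  expect_equal(s@survivalRate, 100 * 10 / 14)
  expect_true(s@singleSession)
  expect_error(summarizeSession(new("SessionRecord", records = data.frame(
    larva_id = 1L, site = "x", mode = "automated", outcome = "skipped",
    reason = "batch_time_budget", t_start = 0, t_end = 0, survived = NA),
    traces = list())), "no larvae")
})

test_that("sessions are bit-reproducible under a fixed seed", {
  p <- generatePlate(nLarvae = 5, imageSize = c(600, 600), seed = 31)
  r1 <- runSession(p, defaultMacro("doc"), seed = 9)
  r2 <- runSession(p, defaultMacro("doc"), seed = 9)
  expect_identical(sessionRecords(r1), sessionRecords(r2))
})

test_that("the Welch one-tailed comparison matches the textbook formula", {
  welchOracle <- function(a, b) {
    # independent hand computation of the Welch statistic and one-tailed p
    na <- length(a); nb <- length(b)
    se2a <- var(a) / na; se2b <- var(b) / nb
    t <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 / (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
    list(t = t, df = df, p = 1 - pt(t, df))
  }
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- compareModes(a, b)
  or <- welchOracle(a, b)
  expect_lt(abs(res$statistic - or$t), 1e-9)
  expect_lt(abs(res$df - or$df), 1e-9)
  expect_lt(abs(res$p.value - or$p), 1e-9)
  set.seed(4)
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1), mean = runif(1, 40, 80), sd = runif(1, 1, 10))
    b <- rnorm(sample(3:8, 1), mean = runif(1, 40, 80), sd = runif(1, 1, 10))
    res <- compareModes(a, b)
    or <- welchOracle(a, b)
    expect_lt(abs(res$p.value - or$p), 1e-9)
  }
  # identical samples: symmetric, p = 0.5
  expect_equal(compareModes(c(60, 70, 80), c(60, 70, 80))$p.value, 0.5)
  expect_equal(compareModes(c(5, 5, 5), c(5, 5, 5))$p.value, 0.5)
  expect_error(compareModes(1, c(1, 2)), "at least 2")
})
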