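test_that("log transformation maps rates to log10 with policy handling", {
  m <- matrix(c(1.0, 4.58, NA, 0), 2, 2,
              dimnames = list(c("e1", "e2"), c("s1", "s2")))
  tab <- activityTable(m, detectionFloor = 1e-3)

  ex <- logActivities(tab, "exclude")
  expect_equal(ex$value[ex$enzyme == "e1" & ex$substrate == "s1"], 0)
  expect_equal(ex$value[ex$enzyme == "e2" & ex$substrate == "s1"],
               log10(4.58), tolerance = 1e-12)
  # below-detection and zero-rate cells are omitted under exclude
  expect_equal(nrow(ex), 2L)
  expect_false(any(ex$floored))

  fl <- logActivities(tab, "floor")
  expect_equal(nrow(fl), 4L)
  flooredCells <- fl[fl$floored, ]
  expect_setequal(flooredCells$substrate, "s2")
  expect_true(all(flooredCells$value == -3))
})

test_that("a planted linear property-activity relation gives r = +1", {
  sc <- builtinScales()$volume
  res8 <- c("G", "A", "S", "C", "V", "I", "F", "W")
  st <- makeStateTable(
    matrix(res8, 8, 1, dimnames = list(sprintf("e%d", 1:8), "166")),
    positions = 166L, clusters = "T")
  la <- data.frame(enzyme = sprintf("e%d", 1:8), substrate = "s1",
                   value = 0.01 * scaleValues(sc)[res8], floored = FALSE)
  res <- positionActivityCorrelation(st, sc, la, "s1")
  expect_identical(res$status, "ok")
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$nUsed, 8L)

  # decreasing activity with size: r = -1 (sign convention)
  la$value <- -la$value
  expect_equal(positionActivityCorrelation(st, sc, la, "s1")$r, -1,
               tolerance = 1e-12)
})

test_that("conserved positions report status, never a numeric r", {
  sc <- builtinScales()$volume
  st <- makeStateTable(
    matrix("G", 5, 1, dimnames = list(sprintf("e%d", 1:5), "91")),
    positions = 91L, clusters = "P")
  la <- data.frame(enzyme = sprintf("e%d", 1:5), substrate = "s1",
                   value = rnorm(5), floored = FALSE)
  res <- positionActivityCorrelation(st, sc, la, "s1")
  expect_identical(res$status, "conserved")
  expect_true(is.na(res$r))
})

test_that("fewer than three usable pairs is insufficient", {
  sc <- builtinScales()$volume
  st <- makeStateTable(
    matrix(c("G", "F", "-", "-"), 4, 1,
           dimnames = list(sprintf("e%d", 1:4), "10")),
    positions = 10L)
  la <- data.frame(enzyme = sprintf("e%d", 1:4), substrate = "s1",
                   value = c(0, 1, 2, 3), floored = FALSE)
  res <- positionActivityCorrelation(st, sc, la, "s1")
  expect_identical(res$status, "insufficient")
  expect_true(is.na(res$r))
  expect_error(positionActivityCorrelation(st, sc, la, "nope"), "absent")
})

test_that("correlations equal the textbook Pearson oracle to 1e-12", {
  set.seed(501)
  sc <- builtinScales()$volume
  for (rep in 1:100) {
    n <- 8
    res <- sample(AA20, n, replace = TRUE)
    while (length(unique(res)) < 2) res <- sample(AA20, n, replace = TRUE)
    st <- makeStateTable(
      matrix(res, n, 1, dimnames = list(sprintf("e%d", 1:n), "1")),
      positions = 1L)
    la <- data.frame(enzyme = sprintf("e%d", 1:n), substrate = "s1",
                     value = rnorm(n), floored = FALSE)
    got <- positionActivityCorrelation(st, sc, la, "s1")
    want <- pearsonOracle(scaleValues(sc)[res], la$value)
    expect_equal(got$r, want, tolerance = 1e-12)
    expect_gte(got$r, -1); expect_lte(got$r, 1)
    # enzyme order permutation leaves r unchanged
    perm <- sample(n)
    la2 <- la[perm, ]
    expect_equal(positionActivityCorrelation(st, sc, la2, "s1")$r, got$r,
                 tolerance = 1e-15)
  }
})

test_that("heatmap matrices carry r for ok cells and sentinels elsewhere", {
  res <- data.frame(
    position = rep(c(166L, 91L), each = 2),
    cluster = rep(c("T", "P"), each = 2),
    substrate = rep(c("s1", "s2"), 2),
    r = c(0.9, -0.4, NA, NA),
    nUsed = c(8L, 8L, 8L, 8L),
    status = c("ok", "ok", "conserved", "conserved"))
  m <- heatmapMatrix(res)
  expect_equal(m["166", "s1"], 0.9)
  expect_equal(m["166", "s2"], -0.4)
  expect_true(all(is.na(m["91", ])))  # conserved row all-sentinel
  expect_identical(attr(m, "status")["91", "s1"], "conserved")

  f <- withr::local_tempfile(fileext = ".tsv")
  writeHeatmapTSV(m, f)
  back <- readHeatmapTSV(f)
  expect_equal(back[rownames(m), colnames(m)],
               m[rownames(m), colnames(m)], tolerance = 1e-12)
  expect_identical(attr(back, "status")[rownames(m), colnames(m)],
                   attr(m, "status"))
})

test_that("combined-property regression recovers a noiseless planted line", {
  sc <- builtinScales()$volume
  res8 <- c("G", "A", "S", "C", "V", "I", "F", "W")
  st <- makeStateTable(
    matrix(c(res8, rev(res8), res8), 8, 3,
           dimnames = list(sprintf("e%d", 1:8), c("166", "392", "427"))),
    positions = c(166L, 392L, 427L))
  comb <- aggregateProperty(st, sc, c(166L, 392L, 427L), "sum")
  la <- data.frame(enzyme = names(comb), substrate = "s1",
                   value = 2 - 0.01 * unname(comb), floored = FALSE)
  fit <- combinedPropertyRegression(st, sc, c(166L, 392L, 427L), la, "s1")
  expect_identical(fit$status, "ok")
  expect_equal(fit$slope, -0.01, tolerance = 1e-9)
  expect_equal(fit$intercept, 2, tolerance = 1e-9)
  expect_equal(fit$r, -1, tolerance = 1e-12)
})

test_that("two usable points are insufficient, not a perfect fit", {
  sc <- builtinScales()$volume
  st <- makeStateTable(
    matrix(c("G", "F"), 2, 1, dimnames = list(c("e1", "e2"), "5")),
    positions = 5L)
  la <- data.frame(enzyme = c("e1", "e2"), substrate = "s1",
                   value = c(0, 1), floored = FALSE)
  fit <- combinedPropertyRegression(st, sc, 5L, la, "s1")
  expect_identical(fit$status, "insufficient")
  expect_true(is.na(fit$r))
})

test_that("regression coefficients match brute-force normal equations", {
  set.seed(502)
  sc <- builtinScales()$volume
  for (rep in 1:50) {
    n <- sample(5:12, 1)
    res <- replicate(3, sample(AA20, n, replace = TRUE))
    st <- makeStateTable(
      matrix(res, n, 3, dimnames = list(sprintf("e%02d", 1:n),
                                        c("1", "2", "3"))),
      positions = 1:3)
    x <- rowSums(matrix(scaleValues(sc)[res], n, 3))
    if (sd(x) == 0) next
    y <- rnorm(n)
    la <- data.frame(enzyme = sprintf("e%02d", 1:n), substrate = "s1",
                     value = y, floored = FALSE)
    fit <- combinedPropertyRegression(st, sc, 1:3, la, "s1")
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(fit$intercept, beta[1], tolerance = 1e-9)
    expect_equal(fit$slope, beta[2], tolerance = 1e-9)
    expect_equal(fit$r, pearsonOracle(x, y), tolerance = 1e-12)
  }
})

test_that("constant combined property flags an undefined slope", {
  sc <- builtinScales()$volume
  st <- makeStateTable(
    matrix("G", 4, 1, dimnames = list(sprintf("e%d", 1:4), "5")),
    positions = 5L)
  la <- data.frame(enzyme = sprintf("e%d", 1:4), substrate = "s1",
                   value = rnorm(4), floored = FALSE)
  fit <- combinedPropertyRegression(st, sc, 5L, la, "s1")
  expect_identical(fit$status, "constant_property")
  expect_true(is.na(fit$slope))
})

test_that("hotspot ranking puts a strong planted position first", {
  set.seed(503)
  sc <- builtinScales()$volume
  n <- 8
  planted <- sample(AA20, n, replace = TRUE)
  while (sd(scaleValues(sc)[planted]) == 0)
    planted <- sample(AA20, n, replace = TRUE)
  neutral <- replicate(3, sample(AA20, n, replace = TRUE))
  m <- cbind(planted, neutral)
  colnames(m) <- c("10", "20", "30", "40")
  rownames(m) <- sprintf("e%d", 1:n)
  st <- makeStateTable(m, c(10L, 20L, 30L, 40L))
  la <- data.frame(enzyme = rownames(m), substrate = "s1",
                   value = 0.02 * scaleValues(sc)[planted] + rnorm(n, 0, 0.05),
                   floored = FALSE)
  res <- positionActivityCorrelation(st, sc, la, "s1")
  rk <- hotspotRanking(res, minAbsR = 0.3, minN = 3L)
  expect_equal(rk$position[1], 10)

  # all-conserved grid: empty ranking
  cons <- res; cons$status <- "conserved"; cons$r <- NA_real_
  expect_equal(nrow(hotspotRanking(cons, minAbsR = 0.3)), 0L)

  # raising the |r| threshold never adds positions
  loose <- hotspotRanking(res, minAbsR = 0.2)
  tight <- hotspotRanking(res, minAbsR = 0.8)
  expect_true(all(tight$position %in% loose$position))
})
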