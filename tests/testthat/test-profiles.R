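test_that("built-in scales cover 20 residues and order side-chain sizes", {
  sc <- builtinScales()
  expect_setequal(names(sc), c("volume", "hydropathy", "polarity"))
  for (s in sc) {
    expect_length(scaleValues(s), 20L)
    expect_true(all(is.finite(scaleValues(s))))
  }
  v <- scaleValues(sc$volume)
  expect_lt(v["G"], v["S"])
  expect_lt(v["S"], v["F"])
})

test_that("shipped hydropathy and polarity match the published aaindex tables", {
  # independent transcription source: seqinr's AAindex database
  e <- new.env()
  data("aaindex", package = "seqinr", envir = e)
  three <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
             Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
             L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
             S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")
  sc <- builtinScales()
  kd <- e$aaindex$KYTJ820101$I
  expect_equal(unname(scaleValues(sc$hydropathy)),
               unname(kd[three[names(scaleValues(sc$hydropathy))]]))
  gr <- e$aaindex$GRAR740102$I
  expect_equal(unname(scaleValues(sc$polarity)),
               unname(gr[three[names(scaleValues(sc$polarity))]]))
})

test_that("shipped residue volumes equal the published total-volume table", {
  # independently re-transcribed from the published table (A^3)
  ref <- c(G = 60.1, A = 88.6, S = 89.0, C = 108.5, D = 111.1, P = 112.7,
           N = 114.1, T = 116.1, E = 138.4, V = 140.0, Q = 143.8,
           H = 153.2, M = 162.9, I = 166.7, L = 166.7, K = 168.6,
           R = 173.4, F = 189.9, Y = 193.6, W = 227.8)
  v <- scaleValues(builtinScales()$volume)
  expect_equal(v[names(ref)], ref)
})

test_that("user scales round-trip through YAML", {
  sc <- builtinScales()$volume
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(name = "volume", units = "A^3",
                        values = as.list(scaleValues(sc))), f)
  back <- readPropertyScale(f)
  expect_equal(scaleValues(back), scaleValues(sc))
})

test_that("diversity profiles are per-clade frequency distributions", {
  st <- makeStateTable(
    matrix(c("G", "G", "G", "G", "G", "F", "S", "D"), 8, 1,
           dimnames = list(paste0("e", 1:8), "392")),
    positions = 392L, clusters = "H")
  clades <- setNames(rep("ox", 8), paste0("e", 1:8))
  prof <- diversityProfiles(st, clades)
  # 5 of the 8 family members carry Gly at the variable H-cluster position
  expect_equal(prof$frequency[prof$residue == "G"], 5 / 8)
  expect_equal(sum(prof$frequency), 1)
  expect_true(all(prof$n == 8L))
})

test_that("single-membership clades give 0/1 frequencies and gaps drop from n", {
  st <- makeStateTable(
    matrix(c("A", "-", "V", "V"), 2, 2,
           dimnames = list(c("e1", "e2"), c("5", "9"))),
    positions = c(5L, 9L))
  prof <- diversityProfiles(st, c(e1 = "c1", e2 = "c2"))
  expect_true(all(prof$frequency %in% c(0, 1)))
  # e2 has a gap at position 5: no profile row for (5, c2)
  expect_false(any(prof$position == 5 & prof$clade == "c2"))
  expect_equal(prof$n[prof$position == 5 & prof$clade == "c1"], 1L)
})

test_that("pooled clades reproduce merged frequencies (brute-force recount)", {
  set.seed(301)
  for (rep in 1:20) {
    n <- sample(6:14, 1)
    st <- makeStateTable(
      matrix(sample(c(AA20, "-"), n * 3, replace = TRUE,
                    prob = c(rep(1, 20), 3)), n, 3,
             dimnames = list(sprintf("e%02d", 1:n), c("1", "2", "3"))),
      positions = 1:3)
    ids <- rownames(siteStates(st))
    twoClades <- setNames(sample(c("x", "y"), n, replace = TRUE), ids)
    oneClade <- setNames(rep("all", n), ids)
    pooled <- diversityProfiles(st, oneClade)
    m <- siteStates(st)
    for (k in seq_len(nrow(pooled))) {
      col <- as.character(pooled$position[k])
      obs <- m[, col]
      obs <- obs[obs != "-"]
      expect_equal(pooled$frequency[k],
                   sum(obs == pooled$residue[k]) / length(obs))
      expect_equal(pooled$n[k], length(obs))
    }
    # per-clade frequencies recombine to the pooled ones (weighted average)
    split <- diversityProfiles(st, twoClades)
    for (k in seq_len(nrow(pooled))) {
      sub <- split[split$position == pooled$position[k] &
                     split$residue == pooled$residue[k], , drop = FALSE]
      cladeN <- split[split$position == pooled$position[k], c("clade", "n")]
      cladeN <- unique(cladeN)
      expect_equal(sum(sub$frequency * sub$n) / sum(cladeN$n),
                   pooled$frequency[k])
    }
  }
})

test_that("property aggregation is additive and matches brute-force lookup", {
  sc <- builtinScales()$volume
  st <- makeStateTable(
    matrix("G", 2, 3, dimnames = list(c("e1", "e2"), c("1", "2", "3"))),
    positions = 1:3)
  expect_equal(unname(aggregateProperty(st, sc, 1L, "sum")),
               rep(scaleValues(sc)[["G"]], 2))
  expect_equal(unname(aggregateProperty(st, sc, 1:3, "sum")),
               rep(3 * scaleValues(sc)[["G"]], 2))

  set.seed(302)
  for (rep in 1:50) {
    n <- sample(3:10, 1)
    m <- matrix(sample(c(AA20, "-", "X"), n * 3, replace = TRUE), n, 3,
                dimnames = list(sprintf("e%02d", 1:n), c("1", "2", "3")))
    st <- makeStateTable(m, 1:3)
    got <- aggregateProperty(st, sc, 1:3, "sum")
    v <- scaleValues(sc)
    want <- apply(m, 1, function(row) {
      if (any(!(row %in% names(v)))) NA_real_ else sum(v[row])
    })
    expect_equal(got, want)
    # permutation invariance over positions
    expect_equal(unname(aggregateProperty(st, sc, c(3L, 1L, 2L), "sum")),
                 unname(got))
  }
})

test_that("gap or X states make a sequence ineligible, never zero", {
  sc <- builtinScales()$volume
  st <- makeStateTable(
    matrix(c("G", "-", "G", "X"), 2, 2,
           dimnames = list(c("e1", "e2"), c("1", "2"))),
    positions = 1:2)
  a <- aggregateProperty(st, sc, 1:2, "sum")
  expect_false(is.na(a[["e1"]]))
  expect_true(is.na(a[["e2"]]))
})

test_that("candidate selection ranks small-volume tunnels first", {
  st <- makeStateTable(
    matrix(c("G", "F", "G", "F", "G", "F"), 2, 3, byrow = FALSE,
           dimnames = list(c("wide", "narrow"), c("165", "166", "427"))),
    positions = c(165L, 166L, 427L), clusters = rep("T", 3))
  crit <- list(selectionCriterion("T", "volume", "sum", "<=", 400))
  sel <- selectCandidates(st, crit)
  expect_identical(sel$enzyme, c("wide", "narrow"))
  expect_true(sel$passAll[sel$enzyme == "wide"])
  expect_false(sel$passAll[sel$enzyme == "narrow"])

  # threshold below the attainable minimum: empty pass set
  crit2 <- list(selectionCriterion("T", "volume", "sum", "<=", 10))
  expect_false(any(selectCandidates(st, crit2)$passAll))

  expect_error(selectCandidates(st, list(
    selectionCriterion("Z", "volume", "sum", "<=", 1))), "unknown cluster")
})

test_that("pass/fail equals brute-force predicate evaluation", {
  set.seed(303)
  sc <- builtinScales()
  for (rep in 1:30) {
    n <- sample(4:10, 1)
    m <- matrix(sample(AA20, n * 4, replace = TRUE), n, 4,
                dimnames = list(sprintf("e%02d", 1:n),
                                as.character(1:4)))
    st <- makeStateTable(m, 1:4, clusters = c("T", "T", "W", "W"))
    crit <- list(
      selectionCriterion("T", "volume", "sum", "<=", runif(1, 100, 500)),
      selectionCriterion("W", "polarity", "mean", ">=", runif(1, 5, 12)))
    sel <- selectCandidates(st, crit, sc)
    for (i in seq_len(nrow(sel))) {
      e <- sel$enzyme[i]
      vT <- sum(scaleValues(sc$volume)[m[e, 1:2]])
      pW <- mean(scaleValues(sc$polarity)[m[e, 3:4]])
      expect_identical(sel$pass.1[i], vT <= crit[[1]]$threshold)
      expect_identical(sel$pass.2[i], pW >= crit[[2]]$threshold)
    }
    # deterministic total ranking: first criterion ascending, ties by ID
    expect_identical(order(sel[[2]], sel$enzyme), seq_len(nrow(sel)))
  }
})
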