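# rotation about z by theta
.rotz <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

test_that("model selection picks the highest mean confidence, ties to first", {
  mk <- function(id, plddt) ca_structure(id, matrix(rnorm(30), 10, 3), plddt)
  set.seed(21)
  models <- list(mk("m1", rep(62.1, 10)), mk("m2", rep(78.4, 10)),
                 mk("m3", rep(71.0, 10)))
  expect_equal(select_best_model(models)$protein_id, "m2")
  expect_equal(select_best_model(models[1])$protein_id, "m1")
  tied <- select_best_model(list(mk("t1", rep(70, 10)), mk("t2", rep(70, 10))))
  expect_equal(tied$protein_id, "t1")
  expect_true(attr(tied, "tie"))
  expect_error(select_best_model(list()), "no models")
})

test_that("Kabsch superposition recovers exact transforms", {
  set.seed(31)
  A <- matrix(rnorm(45), 15, 3) * 5
  # structure vs itself: identity, zero RMSD
  fit <- kabsch_superpose(A, A)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
  # 90 degrees about z: recovered rotation inverts the applied one
  B <- A %*% t(.rotz(pi / 2))
  fit <- kabsch_superpose(B, A)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation %*% .rotz(pi / 2), diag(3), tolerance = 1e-10)
})

test_that("Kabsch matches a rotation-space search oracle on a noisy square", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0) * 3
  noisy <- withr::with_seed(9, sq + matrix(rnorm(12, sd = 0.1), 4, 3))
  fit <- kabsch_superpose(noisy, sq)
  # oracle: coarse Euler-angle grid followed by Nelder-Mead refinement
  cn <- sweep(noisy, 2, colMeans(noisy))
  cs <- sweep(sq, 2, colMeans(sq))
  euler <- function(v) .rotz(v[1]) %*%
    matrix(c(cos(v[2]), 0, sin(v[2]), 0, 1, 0, -sin(v[2]), 0, cos(v[2])),
           3, 3, byrow = TRUE) %*%
    matrix(c(1, 0, 0, 0, cos(v[3]), -sin(v[3]), 0, sin(v[3]), cos(v[3])),
           3, 3, byrow = TRUE)
  obj <- function(v) sqrt(mean(rowSums((cn %*% t(euler(v)) - cs)^2)))
  grid <- as.matrix(expand.grid(a = seq(-pi, pi, length.out = 13),
                                b = seq(-pi / 2, pi / 2, length.out = 7),
                                c = seq(-pi, pi, length.out = 13)))
  vals <- apply(grid, 1, obj)
  ref <- stats::optim(grid[which.min(vals), ], obj,
                      control = list(reltol = 1e-14, maxit = 5000))
  expect_lte(fit$rmsd, min(vals) + 1e-9)     # never worse than the grid
  expect_equal(fit$rmsd, ref$value, tolerance = 1e-3)
})

test_that("Kabsch rejects degenerate inputs and returns proper rotations", {
  A <- matrix(rnorm(9), 3, 3)
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), ">= 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
  set.seed(41)
  for (i in 1:20) {
    M <- matrix(rnorm(30), 10, 3)
    Fx <- matrix(rnorm(30), 10, 3)
    expect_equal(det(kabsch_superpose(M, Fx)$rotation), 1, tolerance = 1e-9)
  }
})

test_that("d0 has its closed-form value at the default normalization", {
  expect_equal(tm_d0(140), 4.4, tolerance = 1e-12) # 1.24 * 125^(1/3) - 1.8
  expect_equal(tm_d0(16), 0.5)      # floored
  expect_error(tm_d0(15), "l_norm")
})

test_that("TM-score is 1 for identical structures and 0.5 at uniform distance d0", {
  refs <- synthetic_reference_set()
  r <- refs$structures$Coh1
  full <- cbind(1:140, 1:140)
  expect_equal(tm_score(r, r, full, 140)$tm, 1.0, tolerance = 1e-12)
  # 140 pairs all at distance d after the optimal superposition: the
  # (+,-,-,+) z-displacement blocks have zero mean and first moments, so
  # the identity is optimal and TM = 1 / (1 + (d/d0)^2)
  zig <- cbind(3.8 * 1:140, rep(c(1, -1), 70), 0)
  pat <- rep(c(1, -1, -1, 1), 35)
  d0 <- tm_d0(140)
  expect_equal(tm_score(zig + cbind(0, 0, d0 * pat), zig, full, 140)$tm, 0.5,
               tolerance = 1e-9)
})

test_that("TM-score is invariant under rigid motion of the query", {
  refs <- synthetic_reference_set()
  r <- refs$structures$Coh2
  moved <- r %*% t(.rotz(0.7)) + matrix(c(12, -7, 30), 140, 3, byrow = TRUE)
  expect_equal(align_and_score(moved, r)$tm, 1.0, tolerance = 1e-9)
  res <- align_and_score(moved, refs$structures$Coh3)
  base <- align_and_score(r, refs$structures$Coh3)
  expect_equal(res$tm, base$tm, tolerance = 1e-6)
  expect_equal(det(res$rotation), 1, tolerance = 1e-9)
})

test_that("the aligner equals exhaustive enumeration on tiny structures", {
  enum_best <- function(q, r, l_norm) {
    n <- nrow(q); m <- nrow(r); best <- -Inf
    for (k in 3:min(n, m)) {
      qs <- utils::combn(n, k); rs <- utils::combn(m, k)
      for (a in seq_len(ncol(qs))) for (b in seq_len(ncol(rs))) {
        tm <- tryCatch(tm_score(q, r, cbind(qs[, a], rs[, b]), l_norm)$tm,
                       error = function(e) -Inf)
        if (tm > best) best <- tm
      }
    }
    best
  }
  base <- withr::with_seed(5, matrix(rnorm(18), 6, 3) * 4)
  q1 <- withr::with_seed(6, base + matrix(rnorm(18, sd = 0.4), 6, 3))
  expect_equal(align_and_score(q1, base, l_norm = 20, min_residues = 4)$tm,
               enum_best(q1, base, 20), tolerance = 1e-6)
  # with a deleted residue (unequal lengths)
  q2 <- withr::with_seed(7, base + matrix(rnorm(18, sd = 0.3), 6, 3))[-3, ]
  expect_equal(align_and_score(q2, base, l_norm = 20, min_residues = 4)$tm,
               enum_best(q2, base, 20), tolerance = 1e-6)
})

test_that("identity calls use strict threshold and fixed-order argmax", {
  sc <- c(Coh1 = 0.72, Coh2 = 0.55, Coh3 = 0.31, CBM3 = 0.28)
  expect_equal(call_domain_from_scores(sc)$call, "Coh1")
  expect_equal(call_domain_from_scores(sc / 2)$call, "NO_MATCH")
  # boundary: exactly 0.50 is not a match
  expect_equal(call_domain_from_scores(
    c(Coh1 = 0.50, Coh2 = 0.1, Coh3 = 0.1, CBM3 = 0.1))$call, "NO_MATCH")
  tied <- call_domain_from_scores(
    c(Coh1 = 0.51, Coh2 = 0.51, Coh3 = 0.2, CBM3 = 0.2))
  expect_equal(tied$call, "Coh1")
  expect_true(tied$tie)
})

test_that("a uniform-distance construction flips the call exactly at d0", {
  zig <- cbind(3.8 * 1:140, rep(c(1, -1), 70), 0)
  pat <- rep(c(1, -1, -1, 1), 35)
  full <- cbind(1:140, 1:140)
  d0 <- tm_d0(140)
  tm_at <- function(d) {
    tm_score(zig + cbind(0, 0, d * pat), zig, full, 140)$tm
  }
  lo <- c(Coh1 = tm_at(d0 * 0.999), Coh2 = 0.1, Coh3 = 0.1, CBM3 = 0.1)
  hi <- c(Coh1 = tm_at(d0 * 1.001), Coh2 = 0.1, Coh3 = 0.1, CBM3 = 0.1)
  expect_equal(call_domain_from_scores(lo)$call, "Coh1")
  expect_equal(call_domain_from_scores(hi)$call, "NO_MATCH")
})

test_that("synthetic reference folds are mutually dissimilar", {
  refs <- synthetic_reference_set()
  nm <- names(refs$structures)
  for (i in 1:3) for (j in (i + 1):4) {
    tm <- align_and_score(refs$structures[[i]], refs$structures[[j]])$tm
    expect_lt(tm, 0.5)
  }
  # and negatives stay below threshold against every reference
  for (kind in c("extended", "three_helix")) {
    neg <- generate_negative_structure(kind, 140, seed = 3)
    expect_equal(assign_domain_identity(neg, refs)$call, "NO_MATCH")
  }
})

test_that("rescue adds typed cohesins for fold matches and reclassifies", {
  refs <- synthetic_reference_set()
  seg_len <- 140L
  mk_candidate <- function(k, pid) {
    doms <- data.frame(
      label = c(rep("COH_LIKE_FOLD", k), "DOC1"),
      start = c(sapply(0:(k - 1), function(i) i * (seg_len + 10L) + 1L),
                k * (seg_len + 10L) + 1L),
      end = c(sapply(0:(k - 1), function(i) i * (seg_len + 10L) + seg_len),
              k * (seg_len + 10L) + 60L))
    len <- max(doms$end) + 5L
    arch <- build_architectures(cbind(protein_id = pid, doms),
                                stats::setNames(len, pid))[[pid]]
    xyz <- matrix(0, len, 3)
    for (i in 0:(k - 1)) {
      rows <- (i * (seg_len + 10L) + 1L):(i * (seg_len + 10L) + seg_len)
      xyz[rows, ] <- refs$structures$Coh1 +
        matrix(c(300 * i, 0, 0), seg_len, 3, byrow = TRUE)
    }
    rest <- rowSums(abs(xyz)) == 0
    xyz[rest, ] <- cbind(3.4 * seq_len(sum(rest)), 900, 900)
    segs <- lapply(0:(k - 1), function(i) {
      (i * (seg_len + 10L) + 1L):(i * (seg_len + 10L) + seg_len)
    })
    list(arch = arch, structure = ca_structure(pid, xyz), segments = segs)
  }
  cand <- mk_candidate(2L, "p1")
  res <- rescue_cohesins(stats::setNames(list(cand$arch), "p1"),
                         list(p1 = cand$structure),
                         segments = list(p1 = cand$segments), refs = refs,
                         organism_id = "org")
  # exactly k cohesins recovered; the protein re-enters the decision tree
  expect_equal(res$cohesins["p1", "seq_cohesins"], 0L)
  expect_equal(res$cohesins["p1", "structure_cohesins"], 2L)
  expect_equal(res$tally_before$n_scaffoldins, 0L)
  expect_equal(res$tally_after$counts[["POLYVALENT_ADAPTOR"]], 1L)
  expect_true(all(res$scores$call == "Coh1"))

  # segments that match nothing leave the architecture unchanged
  neg <- generate_negative_structure("three_helix", sum(lengths(cand$segments)) +
                                       cand$arch$length, seed = 5)
  res2 <- rescue_cohesins(stats::setNames(list(cand$arch), "p1"),
                          list(p1 = ca_structure("p1", neg$xyz[seq_len(cand$arch$length), ])),
                          segments = list(p1 = cand$segments), refs = refs,
                          organism_id = "org")
  expect_equal(res2$cohesins["p1", "structure_cohesins"], 0L)
  expect_equal(res2$tally_after$n_scaffoldins, 0L)

  # candidates without structures are skipped and logged
  res3 <- rescue_cohesins(stats::setNames(list(cand$arch), "p1"),
                          structures = list(), refs = refs, organism_id = "org")
  expect_equal(res3$skipped, "p1")
  expect_equal(res3$tally_after$n_scaffoldins, 0L)
})

test_that("C-alpha PDB files round-trip coordinates and confidences", {
  refs <- synthetic_reference_set()
  st <- ca_structure("ref_coh1", refs$structures$Coh1,
                     plddt = seq(50, 99.5, length.out = 140))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ca_pdb(st, path)
  back <- read_ca_pdb(path)
  expect_equal(back$xyz, st$xyz, tolerance = 1e-3)   # PDB fixed-width rounding
  expect_equal(back$plddt, st$plddt, tolerance = 0.01)
  expect_equal(nrow(back$xyz), 140L)
})
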