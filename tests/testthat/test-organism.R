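# build a tally/profile pair from an explicit architecture list
.org_pair <- function(archs, id = "org") {
  list(tally = tally_scaffoldins(archs, id),
       profile = tabulate_enzyme_profile(archs, organism_id = id))
}

test_that("the prescan truth table holds", {
  docgh <- mk_arch(c("DOC1", "GH48"), "e1")
  # >= 2 cohesins on one protein AND >= 1 DocGH: pass
  x <- .org_pair(list(mk_arch(c("COH1", "COH1"), "s1"), docgh))
  expect_true(prescan_filter(x$tally, x$profile)$pass)
  # many DocGHs but no multi-cohesin protein: fail
  x <- .org_pair(c(list(mk_arch("COH1", "s1")),
                   lapply(1:5, function(i) mk_arch(c("DOC1", "GH48"),
                                                   paste0("e", i)))))
  res <- prescan_filter(x$tally, x$profile)
  expect_false(res$pass)
  expect_match(res$reasons, "multi-cohesin")
  # a 4-cohesin scaffoldin but no DocGH: fail
  x <- .org_pair(list(mk_arch(c("CBM3", rep("COH1", 4)), "s1"),
                      mk_arch(c("DOC1", "CBM3"), "f1")))
  res <- prescan_filter(x$tally, x$profile)
  expect_false(res$pass)
  expect_match(res$reasons, "dockerin-fused GH")
})

test_that("organisms type as complex, simple or scaffoldin-containing", {
  docgh <- function(i) mk_arch(c("DOC1", "GH48"), paste0("e", i))
  # anchoring + complex primary: COMPLEX
  x <- .org_pair(list(
    mk_arch(c("COH1", "COH1", "CBM3", rep("COH1", 7), "DOC2"), "scaA"),
    mk_arch(c("SLH", "COH2"), "scaF"), mk_arch(c("SLH", "COH2"), "scaB"),
    mk_arch(c("CU_AMINE_OXIDASE", "COH1"), "scaG"),
    mk_arch(c("DOC1", "COH1"), "adA"), docgh(1)))
  ty <- type_organism(x$tally, x$profile)
  expect_equal(ty$producer_class, "COMPLEX")
  expect_match(ty$evidence, "anchoring", all = FALSE)
  # a lone 5-cohesin simple primary: SIMPLE
  x <- .org_pair(list(mk_arch(c("CBM3", rep("COH1", 5)), "cipA"), docgh(1)))
  expect_equal(type_organism(x$tally, x$profile)$producer_class, "SIMPLE")
  # anchoring + polyvalent adaptor but no primary: still COMPLEX
  x <- .org_pair(list(mk_arch(c("SLH", "COH2", "COH2"), "anc"),
                      mk_arch(c("DOC1", "COH1", "COH1", "COH1"), "poly"),
                      docgh(1)))
  expect_equal(type_organism(x$tally, x$profile)$producer_class, "COMPLEX")
  # largest scaffoldin has 2 cohesins, no primary, no anchoring pair
  x <- .org_pair(list(mk_arch(c("DOC1", "COH1", "COH1"), "p1"),
                      mk_arch(c("DOC1", "COH1"), "m1"), docgh(1)))
  expect_equal(type_organism(x$tally, x$profile)$producer_class,
               "SCAFFOLDIN_CONTAINING")
  # a 3-cohesin dockerin-free scaffoldin counts as conventional capacity
  x <- .org_pair(list(mk_arch(rep("COH1", 3), "cf"), docgh(1)))
  expect_equal(type_organism(x$tally, x$profile)$producer_class, "SIMPLE")
})

test_that("prescan-failing organisms are NON_PRODUCER with reasons logged", {
  x <- .org_pair(list(mk_arch(c("COH1", "COH1"), "s1")))
  ty <- type_organism(x$tally, x$profile)
  expect_equal(ty$producer_class, "NON_PRODUCER")
  expect_true(is.na(ty$docgh_lcb_level))
  expect_match(ty$evidence, "prescan fail", all = FALSE)
})

test_that("typing is monotone under adding/removing diagnostic content", {
  docgh <- mk_arch(c("DOC1", "GH48"), "e1")
  simple <- list(mk_arch(c("CBM3", rep("COH1", 5)), "cipA"), docgh)
  x <- .org_pair(simple)
  expect_equal(type_organism(x$tally, x$profile)$producer_class, "SIMPLE")
  # add an anchoring scaffoldin plus a polyvalent adaptor: COMPLEX
  complexed <- c(simple, list(mk_arch(c("SLH", "COH2"), "anc"),
                              mk_arch(c("DOC2", "COH2", "COH2"), "poly")))
  x <- .org_pair(complexed)
  expect_equal(type_organism(x$tally, x$profile)$producer_class, "COMPLEX")
  # remove every DocGH protein: NON_PRODUCER
  x <- .org_pair(complexed[-2])
  expect_equal(type_organism(x$tally, x$profile)$producer_class, "NON_PRODUCER")
})

test_that("DocGH-LCB levels follow the high/low bands with an explicit gap", {
  prof <- function(n) {
    structure(list(organism_id = "o", docgh_lcb = n), class = "enzyme_profile")
  }
  expect_equal(docgh_lcb_level(prof(40L)), "HIGH")
  expect_equal(docgh_lcb_level(prof(22L)), "HIGH")
  expect_equal(docgh_lcb_level(prof(70L)), "HIGH")
  expect_equal(docgh_lcb_level(prof(2L)), "LOW")
  expect_equal(docgh_lcb_level(prof(10L)), "LOW")
  expect_equal(docgh_lcb_level(prof(15L)), "INTERMEDIATE")
  expect_equal(docgh_lcb_level(prof(11L)), "INTERMEDIATE")
  expect_equal(docgh_lcb_level(prof(21L)), "INTERMEDIATE")
  expect_error(docgh_lcb_level(prof(-1L)), "negative")
})

test_that("complementarity audit flags orphan cohesin/dockerin types", {
  # Coh2 modules with no Doc2 partner anywhere (the R. hungatei situation)
  archs <- list(mk_arch(c("COH2", "COH2", "FN3"), "a"),
                mk_arch(c("COH2", "FN3"), "b"),
                mk_arch(c("DOC1", "GH48"), "c"))
  rep <- cohesin_dockerin_complementarity(archs)
  expect_equal(rep$coh[["COH2"]], 3L)
  expect_equal(rep$doc[["DOC2"]], 0L)
  expect_true(rep$orphan_coh[["COH2"]])
  expect_true(rep$orphan_doc[["DOC1"]])
  # balanced types: no orphans
  archs <- list(mk_arch(rep("COH1", 5), "a"),
                mk_arch(c("DOC1", "GH48"), "b"), mk_arch(c("DOC1", "GH9"), "c"))
  rep <- cohesin_dockerin_complementarity(archs)
  expect_equal(rep$coh[["COH1"]], 5L)
  expect_false(any(rep$orphan_coh))
  expect_false(any(rep$orphan_doc))
  # empty organism: all zero, no orphans
  rep <- cohesin_dockerin_complementarity(list())
  expect_equal(sum(rep$coh) + sum(rep$doc), 0L)
  expect_false(any(rep$orphan_coh | rep$orphan_doc))
})

.prof <- function(id, dock, lcb) {
  structure(list(organism_id = id, dockerin_proteins = dock, docgh_lcb = lcb),
            class = "enzyme_profile")
}

test_that("the dockerin ~ DocGH-LCB regression matches closed forms", {
  # perfectly collinear points
  fit <- dockerin_vs_docghlcb_regression(
    list(.prof("a", 1, 1), .prof("b", 2, 2), .prof("c", 3, 3)))
  expect_equal(fit$r_squared, 1.0)
  expect_equal(fit$slope, 1.0)
  expect_equal(fit$intercept, 0.0)
  # closed form: Sxy^2 / (Sxx * Syy) = 1^2 / (2 * 2/3) = 0.75
  fit <- dockerin_vs_docghlcb_regression(
    list(.prof("a", 1, 1), .prof("b", 2, 2), .prof("c", 3, 2)))
  expect_equal(fit$r_squared, 0.75)
  expect_equal(fit$n, 3L)
})

test_that("regression R^2 is order-invariant and axis-symmetric", {
  set.seed(7)
  profs <- lapply(1:12, function(i) {
    d <- sample(5:200, 1)
    .prof(paste0("o", i), d, round(0.3 * d + rnorm(1, sd = 5)))
  })
  f1 <- dockerin_vs_docghlcb_regression(profs)
  f2 <- dockerin_vs_docghlcb_regression(rev(profs))
  expect_equal(f1$r_squared, f2$r_squared)
  # swapping predictor and response leaves R^2 (Pearson identity) unchanged
  swapped <- lapply(profs, function(p) .prof(p$organism_id, p$docgh_lcb,
                                             p$dockerin_proteins))
  expect_equal(dockerin_vs_docghlcb_regression(swapped)$r_squared, f1$r_squared)
})

test_that("degenerate regressions are rejected", {
  expect_error(dockerin_vs_docghlcb_regression(list(.prof("a", 1, 1),
                                                    .prof("b", 2, 2))),
               "at least 3")
  expect_error(dockerin_vs_docghlcb_regression(
    list(.prof("a", 5, 1), .prof("b", 5, 2), .prof("c", 5, 3))),
    "zero variance")
})
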