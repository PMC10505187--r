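calls_fixture <- data.frame(
  sgrna_id = c("sg_pgrR", "sg_metJ", "sg_crp", "sg_fur"),
  promoter_id = c("PpgrR", "PmetA", "PlacZ", "Pfur"),
  target_tf = c("pgrR", "metJ", "crp", "fur"),
  Z = c(8, 6, -5, 0.3), p = c(1e-9, 1e-8, 1e-7, 0.7),
  q = c(1e-7, 1e-6, 1e-5, 0.9),
  fold_vs_control = c(3.1, 2.4, 0.4, 1.05),
  fold_vs_median = c(2.9, 2.2, 0.45, 1.02),
  call = c("up", "up", "down", "ns"), stringsAsFactors = FALSE)

promoters_fixture <- data.frame(
  promoter_id = c("PpgrR", "PmetA", "PlacZ", "Pfur"),
  operon = c("pgrR", "metA", "lacZ", "fur"),
  genes = c("pgrR", "metA", "lacZ", "fur"),
  tf_gene_of_promoter = c("pgrR", "", "", "fur"),
  stringsAsFactors = FALSE)

test_that("knockdown direction maps to the regulatory sign", {
  edges <- build_network(calls_fixture, condition = "glucose")
  expect_equal(nrow(edges), 3)  # exactly the non-ns calls
  expect_identical(edges$sign[edges$tf == "pgrR"], "repression")
  expect_identical(edges$sign[edges$tf == "metJ"], "repression")
  expect_identical(edges$sign[edges$tf == "crp"], "activation")
  expect_true(all(edges$condition == "glucose"))

  none <- calls_fixture
  none$call <- "ns"
  expect_equal(nrow(build_network(none)), 0)
})

test_that("autoregulation keeps only a TF acting on its own promoter", {
  edges <- build_network(calls_fixture, "glucose")
  auto <- autoregulation(edges, promoters_fixture)
  # pgrR knocks down its own promoter; metJ acts on metA (not its own);
  # fur's promoter carries fur but the fur call was ns
  expect_identical(auto$tf, "pgrR")
  expect_identical(auto$sign, "repression")
})

test_that("condition overlap partitions tuples like exhaustive enumeration", {
  e <- function(tf, pr, sign) data.frame(tf = tf, promoter_id = pr,
                                         sign = sign,
                                         stringsAsFactors = FALSE)
  glu <- rbind(e("a", "P1", "repression"), e("b", "P2", "activation"),
               e("c", "P3", "repression"))
  gly <- rbind(e("a", "P1", "repression"), e("d", "P4", "repression"))
  lb  <- rbind(e("a", "P1", "repression"), e("e", "P5", "activation"))
  ov <- condition_overlap(list(glucose = glu, glycerol = gly, LB = lb))

  # independent brute-force enumeration over the union of tuples
  all_edges <- rbind(cbind(glu, cond = "glucose"),
                     cbind(gly, cond = "glycerol"),
                     cbind(lb, cond = "LB"))
  tup <- unique(all_edges[, c("tf", "promoter_id", "sign")])
  expected <- table(apply(tup, 1, function(t) {
    inset <- c(any(glu$tf == t[1] & glu$promoter_id == t[2]),
               any(gly$tf == t[1] & gly$promoter_id == t[2]),
               any(lb$tf == t[1] & lb$promoter_id == t[2]))
    paste(c("glucose", "glycerol", "LB")[inset], collapse = "+")
  }))
  for (pat in names(expected)) {
    expect_equal(sum(ov$count[ov$membership_pattern == pat]),
                 unname(expected[pat]))
  }
  expect_equal(sum(ov$count), nrow(tup))

  # identical sets: everything in the triple intersection
  same <- condition_overlap(list(c1 = glu, c2 = glu, c3 = glu))
  expect_true(all(same$membership_pattern == "c1+c2+c3"))
  expect_equal(sum(same$count), 3)

  # disjoint sets: no multi-condition pattern appears
  disj <- condition_overlap(list(c1 = e("a", "P1", "repression"),
                                 c2 = e("b", "P2", "repression")))
  expect_false(any(grepl("+", disj$membership_pattern, fixed = TRUE)))
})

sites_fixture <- data.frame(
  tf = c("metJ", "metJ", "metJ", "fur", "fur"),
  promoter_id = c("PmetA", "PmetA", "PmetE", "PmetA", "Pfur"),
  site_start = c(100, 140, 80, 300, 50),
  site_end = c(120, 160, 100, 320, 70),
  fold_enrichment = c(3, 7, 14, 2, 8),
  tss_position = c(150, 150, 90, 150, 40),
  stringsAsFactors = FALSE)

test_that("relative binding keeps the strongest site and normalizes twice", {
  rb <- relative_binding(sites_fixture)
  expect_equal(nrow(rb), 4)  # one row per (tf, promoter)
  metj_meta <- rb[rb$tf == "metJ" & rb$promoter_id == "PmetA", ]
  expect_equal(metj_meta$fold_enrichment, 7)  # 3 discarded
  # per TF: metJ's max over promoters is 14
  expect_equal(metj_meta$rel_strength_per_tf, 0.5)
  expect_equal(rb$rel_strength_per_tf[rb$tf == "metJ" &
                                        rb$promoter_id == "PmetE"], 1)
  # per promoter: PmetA's strongest TF is metJ at 7
  expect_equal(metj_meta$rel_strength_per_promoter, 1)
  expect_equal(rb$rel_strength_per_promoter[rb$tf == "fur" &
                                              rb$promoter_id == "PmetA"],
               2 / 7)
  # midpoint of [140, 160) is 150 = the TSS
  expect_equal(metj_meta$tss_relative_center, 0)
  expect_true(all(rb$rel_strength_per_tf > 0 & rb$rel_strength_per_tf <= 1))
})

test_that("relative binding is scale-invariant and drops unknown promoters", {
  rb1 <- relative_binding(sites_fixture)
  scaled <- sites_fixture
  scaled$fold_enrichment <- scaled$fold_enrichment * 37
  rb2 <- relative_binding(scaled)
  expect_equal(rb1$rel_strength_per_tf, rb2$rel_strength_per_tf)
  expect_equal(rb1$rel_strength_per_promoter, rb2$rel_strength_per_promoter)

  expect_warning(
    rb3 <- relative_binding(sites_fixture,
                            promoter_ids = c("PmetA", "PmetE")),
    "unknown")
  expect_false("Pfur" %in% rb3$promoter_id)
})

test_that("regulating vs non-regulating comparison detects a shifted feature", {
  set.seed(71)
  n <- 50
  binding <- data.frame(
    tf = paste0("tf", 1:(2 * n)),
    promoter_id = paste0("P", 1:(2 * n)),
    fold_enrichment = 5,
    rel_strength_per_tf = runif(2 * n),
    rel_strength_per_promoter = c(runif(n, 0.5, 1), runif(n, 0, 0.5)),
    tss_relative_center = rnorm(2 * n, 0, 40),
    stringsAsFactors = FALSE)
  edges <- data.frame(tf = paste0("tf", 1:n),
                      promoter_id = paste0("P", 1:n),
                      sign = "repression", stringsAsFactors = FALSE)
  res <- regulating_vs_nonregulating(binding, edges)
  strong <- res[res$feature == "rel_strength_per_promoter", ]
  expect_lt(strong$p_adj, 0.01)
  expect_gt(strong$median_regulating, strong$median_nonregulating)
  ann <- attr(res, "annotated")
  expect_equal(sum(ann$regulating), n)

  # no edges at all: everything non-regulating, tests undefined
  res0 <- regulating_vs_nonregulating(binding, edges[0, ])
  expect_true(all(is.na(res0$p)))
})

test_that("null features show no systematic significance", {
  set.seed(73)
  hits <- replicate(30, {
    binding <- data.frame(
      tf = paste0("tf", 1:40), promoter_id = paste0("P", 1:40),
      fold_enrichment = 5,
      rel_strength_per_tf = runif(40),
      rel_strength_per_promoter = runif(40),
      tss_relative_center = rnorm(40, 0, 40), stringsAsFactors = FALSE)
    edges <- data.frame(tf = paste0("tf", 1:20),
                        promoter_id = paste0("P", 1:20),
                        sign = "repression", stringsAsFactors = FALSE)
    any(regulating_vs_nonregulating(binding, edges)$p < 0.05, na.rm = TRUE)
  })
  expect_lte(mean(hits), 0.3)
})
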