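mk_design <- function(conds = c("control", "60%", "30%"), control = "control") {
  data.frame(condition = conds, is_control = conds == control,
             stringsAsFactors = FALSE)
}

test_that("comparative Ct arithmetic matches hand calculation", {
  # replicates {20.0, 20.2, 19.8} control / {18.0, 18.2, 17.8} treated,
  # reference constant at 15 -> ddCt = -2, FC = 4
  ct <- rbind(
    data.frame(gene = "t", condition = "control", is_control = TRUE,
               replicate = 1:3, ct = c(20.0, 20.2, 19.8)),
    data.frame(gene = "t", condition = "treat", is_control = FALSE,
               replicate = 1:3, ct = c(18.0, 18.2, 17.8)),
    data.frame(gene = "ref", condition = "control", is_control = TRUE,
               replicate = 1:3, ct = 15),
    data.frame(gene = "ref", condition = "treat", is_control = FALSE,
               replicate = 1:3, ct = 15)
  )
  res <- delta_delta_ct(ct, "ref")
  tt <- res[res$gene == "t" & res$condition == "treat", ]
  expect_equal(tt$delta_delta_ct, -2)
  expect_equal(tt$fold_change, 4)
  expect_equal(tt$direction, "up")
  ctrl <- res[res$gene == "t" & res$condition == "control", ]
  expect_equal(ctrl$fold_change, 1)
  expect_equal(ctrl$direction, "unchanged")

  # a one-cycle drop relative to reference doubles expression
  ct2 <- ct
  ct2$ct[ct2$gene == "t" & ct2$condition == "treat"] <- c(19.0, 19.2, 18.8)
  res2 <- delta_delta_ct(ct2, "ref")
  expect_equal(res2$fold_change[res2$gene == "t" & res2$condition == "treat"], 2)

  # missing reference measurements are reported by condition
  ct3 <- ct[!(ct$gene == "ref" & ct$condition == "treat"), ]
  expect_error(delta_delta_ct(ct3, "ref"), "treat")
})

test_that("reference gene analyzed as target gives FC 1 everywhere", {
  tab <- simulate_ct_table(mk_design(), c("60%" = 3, "30%" = 0.25),
                           noise_sd = 0.3, seed = 12)
  res <- delta_delta_ct(tab, "Actin-7")
  ref_rows <- res[res$gene == "Actin-7", ]
  expect_true(all(ref_rows$fold_change == 1))
})

test_that("noise-free simulated tables return planted fold changes exactly", {
  tab <- simulate_ct_table(mk_design(), c("60%" = 1, "30%" = 1), noise_sd = 0,
                           seed = 1)
  res <- delta_delta_ct(tab, "Actin-7")
  expect_true(all(res$fold_change == 1))

  tab2 <- simulate_ct_table(mk_design(), c("60%" = 2, "30%" = 0.5),
                            noise_sd = 0, seed = 2)
  res2 <- delta_delta_ct(tab2, "Actin-7")
  expect_equal(res2$fold_change[res2$gene == "target" & res2$condition == "60%"], 2)
  expect_equal(res2$fold_change[res2$gene == "target" & res2$condition == "30%"], 0.5)
  expect_equal(res2$direction[res2$gene == "target" & res2$condition == "30%"], "down")

  expect_error(
    simulate_ct_table(data.frame(condition = "a", is_control = FALSE),
                      c(a = 1)),
    "control"
  )
})

test_that("swapping treatment and control inverts the fold change", {
  tab <- simulate_ct_table(mk_design(c("control", "treat")),
                           c(treat = 2.5), noise_sd = 0, seed = 3)
  res <- delta_delta_ct(tab, "Actin-7")
  fc_fwd <- res$fold_change[res$gene == "target" & res$condition == "treat"]
  tab_swapped <- tab
  tab_swapped$is_control <- tab_swapped$condition == "treat"
  res_sw <- delta_delta_ct(tab_swapped, "Actin-7")
  fc_rev <- res_sw$fold_change[res_sw$gene == "target" & res_sw$condition == "control"]
  expect_equal(fc_fwd * fc_rev, 1)
})

test_that("Welch test on dCt: degenerate, symmetric and powered cases", {
  ct <- rbind(
    data.frame(gene = "t", condition = "control", is_control = TRUE,
               replicate = 1:3, ct = c(20, 20.5, 19.5)),
    data.frame(gene = "t", condition = "treat", is_control = FALSE,
               replicate = 1:3, ct = c(20, 20.5, 19.5)),
    data.frame(gene = "ref", condition = "control", is_control = TRUE,
               replicate = 1:3, ct = 15),
    data.frame(gene = "ref", condition = "treat", is_control = FALSE,
               replicate = 1:3, ct = 15)
  )
  expect_equal(ddct_significance(ct, "ref", "t", "treat"), 1)

  # two-sided symmetry under label swap
  ct$ct[ct$gene == "t" & ct$condition == "treat"] <- c(18.1, 18.4, 17.9)
  p1 <- ddct_significance(ct, "ref", "t", "treat")
  ct_sw <- ct
  ct_sw$is_control <- ct_sw$condition == "treat"
  p2 <- ddct_significance(ct_sw, "ref", "t", "control")
  expect_equal(p1, p2)

  # planted ddCt = -3 at noise 0.1 is detected in >= 90% of seeds
  hits <- vapply(1:50, function(s) {
    tab <- simulate_ct_table(mk_design(c("control", "treat")), c(treat = 8),
                             noise_sd = 0.1, n_reps = 3, seed = s)
    ddct_significance(tab, "Actin-7", "target", "treat") < 0.05
  }, NA)
  expect_gte(mean(hits), 0.9)

  # single replicate is not assessable
  ct1 <- ct[ct$replicate == 1, ]
  expect_true(is.na(ddct_significance(ct1, "ref", "t", "treat")))
})

test_that("physiology indices follow their closed forms", {
  expect_equal(rwc(3, 1, 3), 100)
  expect_equal(rwc(1, 1, 3), 0)
  expect_equal(rwc(2, 1, 3), 50)
  expect_error(rwc(2, 2, 2), "undefined")
  expect_error(rwc(1, 2, 3), "WS >= WF >= WD")

  expect_equal(na_k_ratio(10, 10), 1)
  expect_equal(na_k_ratio(20, 10), 2)
  expect_equal(na_k_ratio(3, 7) * na_k_ratio(7, 3), 1)
  expect_error(na_k_ratio(1, 0), "> 0")
})

test_that("heat matrix clusters planted expression blocks", {
  res <- data.frame(
    gene = rep(c("g1", "g2", "g3", "g4"), each = 2),
    condition = rep(c("c1", "c2"), 4),
    fold_change = c(8, 8, 8.2, 8.4, 0.1, 0.12, 0.11, 0.1)
  )
  hm <- heat_matrix(res, k_groups = 2)
  expect_equal(dim(hm$log2fc), c(4, 2))
  expect_equal(hm$groups[["g1"]], hm$groups[["g2"]])
  expect_equal(hm$groups[["g3"]], hm$groups[["g4"]])
  expect_false(hm$groups[["g1"]] == hm$groups[["g3"]])

  all1 <- data.frame(gene = rep(c("a", "b"), each = 2),
                     condition = rep(c("c1", "c2"), 2), fold_change = 1)
  expect_true(all(heat_matrix(all1, 1)$log2fc == 0))

  # identical profiles always co-cluster
  twin <- data.frame(gene = rep(c("a", "b", "c"), each = 2),
                     condition = rep(c("c1", "c2"), 3),
                     fold_change = c(2, 4, 2, 4, 9, 0.5))
  expect_equal(heat_matrix(twin, 2)$groups[["a"]],
               heat_matrix(twin, 2)$groups[["b"]])
  expect_error(heat_matrix(transform(all1, fold_change = 0), 1), "positive")
})
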