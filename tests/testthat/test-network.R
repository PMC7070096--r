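cfg <- pfc_config()

test_that("population allocation hits the column size exactly with the printed anchors", {
  pops <- cell_populations(cfg)
  expect_equal(sum(pops$n), 2000)
  # 900 layer 2/3 pyramidal cells carry the 30x30 image
  expect_equal(pops$n[pops$type == "PC" & pops$layer == "L23"], 900)
  # cross-layer interneurons (BPC + DBC) are 4.1% of the column
  expect_equal(sum(pops$n[pops$type %in% c("BPC", "DBC")]), 82)
  # excitatory share in the 70-80% range
  exc <- sum(pops$n[pops$type == "PC"]) / 2000
  expect_true(exc >= 0.70 && exc <= 0.80)
  # no BPC population in layer 5
  expect_false(any(pops$type == "BPC" & pops$layer == "L5"))
  # largest-remainder rounding is exact for any total
  for (n in c(97, 500, 1999)) {
    expect_equal(sum(cell_populations(cfg, n)$n), n)
  }
})

test_that("column construction is reproducible and respects wiring rules", {
  net1 <- build_column(cfg, seed = 5)
  net2 <- build_column(cfg, seed = 5)
  expect_identical(net1$synapses, net2$synapses)
  expect_identical(net1$neurons, net2$neurons)
  expect_equal(nrow(net1$neurons), 2000)
  syn <- net1$synapses
  # no autapses
  expect_true(all(syn$pre != syn$post))
  # receptor sign respects the presynaptic type
  nn <- net1$neurons
  pre_type <- nn$type[match(syn$pre, nn$id)]
  inh <- pre_type %in% c("ChC", "BPC", "DBC", "LBC", "MC")
  expect_true(all(syn$g_ampa_nS[inh] == 0 & syn$g_nmda_nS[inh] == 0))
  expect_true(all(syn$g_gabaa_nS[!inh] == 0))
  expect_true(all(syn$g_ampa_nS[!inh] > 0))
  # zero-probability rule draws nothing: chandelier cells never target
  # other interneurons in the default table
  post_type <- nn$type[match(syn$post, nn$id)]
  expect_equal(sum(pre_type == "ChC" & post_type != "PC"), 0)
})

test_that("realized synapse counts match N_pre N_post p within binomial error", {
  # aggregate over 20 seeds of a scaled-down column for speed
  mcfg <- mini_config(200)
  pops <- cell_populations(mcfg, 200)
  n_of <- function(ty, ly) {
    k <- pops$n[pops$type == ty & pops$layer == ly]
    if (length(k) == 0) 0 else k
  }
  pick <- list(c("PC", "L23", "PC", "L23"), c("PC", "L23", "ChC", "L23"),
               c("ChC", "L23", "PC", "L23"), c("MC", "L5", "PC", "L23"))
  rules <- pfcmaint:::expand_rules(mcfg)
  tot <- stats::setNames(numeric(length(pick)), sapply(pick, paste, collapse = "."))
  exp_n <- tot
  for (s in 1:20) {
    net <- build_column(mcfg, seed = 100 + s, n_total = 200)
    nn <- net$neurons
    syn <- net$synapses
    pre_ty <- paste(nn$type, nn$layer)[match(syn$pre, nn$id)]
    post_ty <- paste(nn$type, nn$layer)[match(syn$post, nn$id)]
    for (i in seq_along(pick)) {
      p4 <- pick[[i]]
      r <- rules[rules$pre_type == p4[1] & rules$pre_layer == p4[2] &
                   rules$post_type == p4[3] & rules$post_layer == p4[4], ]
      npair <- n_of(p4[1], p4[2]) * n_of(p4[3], p4[4]) -
        (if (p4[1] == p4[3] && p4[2] == p4[4]) n_of(p4[1], p4[2]) else 0)
      exp_n[i] <- exp_n[i] + npair * r$p[1]
      tot[i] <- tot[i] + sum(pre_ty == paste(p4[1], p4[2]) &
                               post_ty == paste(p4[3], p4[4]))
    }
  }
  for (i in seq_along(pick)) {
    sd4 <- 4 * sqrt(exp_n[i])   # 4 sigma on the pooled binomial count
    expect_lt(abs(tot[i] - exp_n[i]), sd4)
  }
})

test_that("multicolumn networks stack exchangeable columns with restricted cross wiring", {
  net1 <- build_multicolumn(cfg, 1, seed = 9)
  expect_equal(nrow(net1$neurons), 2000)
  expect_equal(max(net1$neurons$column), 1)

  net4 <- build_multicolumn(mini_config(300), 4, seed = 9)
  expect_equal(nrow(net4$neurons), 1200)
  nn <- net4$neurons
  syn <- net4$synapses
  pre_col <- nn$column[match(syn$pre, nn$id)]
  post_col <- nn$column[match(syn$post, nn$id)]
  cross <- syn[pre_col != post_col, ]
  expect_gt(nrow(cross), 0)
  # cross-column edges originate exclusively from PC and long-range types
  cross_ty <- nn$type[match(cross$pre, nn$id)]
  expect_true(all(cross_ty %in% c("PC", "LBC", "MC")))
  # explicit rule with a forbidden presynaptic type faults
  bad <- pfcmaint:::expand_rules(cfg)[1, ]
  bad$pre_type <- "ChC"
  expect_error(build_multicolumn(cfg, 2, seed = 1, intercolumn_rules = bad),
               "PC or long-range")
})

test_that("cross-column wiring is statistically symmetric between columns", {
  counts <- sapply(1:20, function(s) {
    net <- build_multicolumn(mini_config(150), 2, seed = 400 + s)
    nn <- net$neurons
    syn <- net$synapses
    pre_col <- nn$column[match(syn$pre, nn$id)]
    post_col <- nn$column[match(syn$post, nn$id)]
    c(sum(pre_col == 1 & post_col == 2), sum(pre_col == 2 & post_col == 1))
  })
  m12 <- sum(counts[1, ]); m21 <- sum(counts[2, ])
  # equal expected counts: difference within 4 sd of the pooled binomial
  expect_lt(abs(m12 - m21), 4 * sqrt(m12 + m21))
})

test_that("ablation removes the targets and every touching synapse, and commutes", {
  net <- build_column(cfg, seed = 21)
  ab <- apply_ablation(net, "LL:L23")
  nn <- ab$neurons
  expect_equal(sum(nn$type == "ChC" & nn$layer == "L23"), 0)
  expect_equal(sum(nn$type == "PC"), 1500)       # PCs untouched
  gone <- setdiff(net$neurons$id, nn$id)
  expect_false(any(ab$synapses$pre %in% gone | ab$synapses$post %in% gone))
  # remaining graph is identical to the original minus the targets
  keep <- !(net$synapses$pre %in% gone | net$synapses$post %in% gone)
  expect_equal(ab$synapses, net$synapses[keep, ], ignore_attr = TRUE)

  # identity on the empty spec
  expect_identical(apply_ablation(net, ablation_spec()), net)
  # empty resolution warns and returns identity
  two <- apply_ablation(net, "LL:L23")
  expect_warning(out <- apply_ablation(two, "LL:L23"), "no neurons")
  expect_identical(out$neurons, two$neurons)

  # commutativity: A then B equals the union spec
  ab_then <- apply_ablation(apply_ablation(net, "CL:L23"), "LR:L23")
  ab_union <- apply_ablation(net, c("CL:L23", "LR:L23"))
  expect_identical(ab_then$neurons$id, ab_union$neurons$id)
  expect_identical(ab_then$synapses, ab_union$synapses)
  # removed count equals the sum of the separate ablations
  n_cl <- nrow(net$neurons) - nrow(apply_ablation(net, "CL:L23")$neurons)
  n_lr <- nrow(net$neurons) - nrow(apply_ablation(net, "LR:L23")$neurons)
  expect_equal(nrow(net$neurons) - nrow(ab_union$neurons), n_cl + n_lr)
})

test_that("configuration faults are rejected", {
  bad <- cfg
  bad$proportions$proportion[1] <- bad$proportions$proportion[1] + 0.05
  expect_error(validate_config(bad), "sum to 1")
  bad2 <- cfg
  bad2$connectivity$g_ampa_nS[bad2$connectivity$pre_type == "ChC"] <- 1
  expect_error(validate_config(bad2), "AMPA")
  bad3 <- cfg
  bad3$receptors$tau_on_ms[1] <- 10
  expect_error(validate_config(bad3), "exceed")
})
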