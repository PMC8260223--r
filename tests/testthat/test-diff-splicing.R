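test_that("dm_loglik matches independent closed forms", {
  # empty sample set: empty product
  expect_equal(dm_loglik(matrix(0, 0, 2), c(0.5, 0.5), 10), 0)
  # n = 1 reduces to the categorical distribution for any phi
  for (phi in c(0.3, 1, 50, 1e4)) {
    expect_equal(dm_loglik(c(1, 0), c(0.5, 0.5), phi), log(0.5))
    expect_equal(dm_loglik(c(0, 1), c(0.2, 0.8), phi), log(0.8))
  }
  # zero proportion with observed count: impossible, -Inf
  expect_equal(dm_loglik(c(2, 1), c(1, 0), 5), -Inf)
  expect_true(is.finite(dm_loglik(c(2, 0), c(1, 0), 5)))

  # 100 random small cases vs the rising-factorial product form
  withr::with_seed(19, {
    for (case in 1:100) {
      J <- sample(2:4, 1)
      S <- sample(1:4, 1)
      y <- matrix(rpois(J * S, 5), nrow = S)
      pi <- rgamma(J, 1) + 0.05
      pi <- pi / sum(pi)
      phi <- runif(1, 0.2, 200)
      expect_equal(dm_loglik(y, pi, phi), dm_loglik_product(y, pi, phi),
                   tolerance = 1e-8)
    }
  })

  # large phi approaches the multinomial log-likelihood
  withr::with_seed(23, {
    y <- matrix(rpois(6, 20), nrow = 2)
    pi <- c(0.3, 0.2, 0.5)
  })
  expect_equal(dm_loglik(y, pi, 1e8), multinomial_loglik(y, pi),
               tolerance = 1e-4)
})

test_that("dm_fit recovers planted proportions and separates conditions", {
  # identical counts in every sample: no condition effect
  y <- matrix(rep(c(50, 50), 4), nrow = 4, byrow = TRUE)
  f0 <- dm_fit(list(a = y[1:2, ], b = y[3:4, ]))
  expect_lt(f0$lrt_stat, 1e-3)
  expect_equal(f0$df, 1L)

  # strong planted separation: pi recovered, statistic far in the tail
  withr::with_seed(29, {
    draw <- function(pi, phi, n, depth) {
      t(vapply(seq_len(n), function(i) {
        p <- rgamma(length(pi), phi * pi)
        p <- p / sum(p)
        as.numeric(rmultinom(1, rpois(1, depth), p))
      }, numeric(length(pi))))
    }
    ya <- draw(c(0.2, 0.8), 50, 3, 500)
    yb <- draw(c(0.8, 0.2), 50, 3, 500)
  })
  f <- dm_fit(list(control = ya, treated = yb))
  expect_lt(max(abs(f$pi["control", ] - c(0.2, 0.8))), 0.1)
  expect_lt(max(abs(f$pi["treated", ] - c(0.8, 0.2))), 0.1)
  expect_gt(f$lrt_stat, qchisq(0.95, 1))
  # proportions normalize and the statistic is non-negative by construction
  expect_equal(rowSums(f$pi), c(control = 1, treated = 1))
  expect_gte(f$lrt_stat, 0)

  # single sample per condition, large-phi limit: pi equals observed
  # proportions
  f1 <- dm_fit(list(a = matrix(c(30, 70), 1), b = matrix(c(60, 40), 1)),
               phi_grid = 1e8)
  expect_equal(unname(f1$pi["a", ]), c(0.3, 0.7), tolerance = 1e-3)
  expect_equal(unname(f1$pi["b", ]), c(0.6, 0.4), tolerance = 1e-3)

  expect_error(dm_fit(list(a = matrix(0, 2, 2), b = matrix(0, 2, 2))),
               "zero")
})

test_that("the LRT is invariant to sample order and label swap", {
  toy <- shared_toy()
  ev <- toy$events
  eid <- unique(ev$event_id[ev$event_type == "AFE"])[1]
  y <- t(toy$counts$counts[ev$row_id[ev$event_id == eid], , drop = FALSE])
  ctl <- y[toy$counts$condition == "control", ]
  trt <- y[toy$counts$condition == "LPS", ]
  f_ab <- dm_fit(list(a = ctl, b = trt))
  f_ba <- dm_fit(list(a = trt, b = ctl))
  f_perm <- dm_fit(list(a = ctl[c(3, 1, 2), ], b = trt[c(2, 3, 1), ]))
  expect_equal(f_ab$lrt_stat, f_ba$lrt_stat, tolerance = 1e-6)
  expect_equal(f_ab$lrt_stat, f_perm$lrt_stat, tolerance = 1e-6)
})

test_that("t-test route gates on delta and flags clear separations", {
  ann <- make_annotation(
    list(gene = "g", tx = "t1", strand = "+",
         exons = ex(0, 200, 5000, 5200)),
    list(gene = "g", tx = "t2", strand = "+",
         exons = ex(1000, 1200, 5000, 5200)))
  ev <- build_events(ann)
  mk_psi <- function(ctl, trt) {
    m <- rbind(ctl, 100 - ctl)
    m <- cbind(m, rbind(trt, 100 - trt))
    counts <- round(m * 2)
    rownames(counts) <- ev$row_id
    colnames(counts) <- c(paste0("c", seq_along(ctl)),
                          paste0("t", seq_along(trt)))
    ct <- count_table(counts, setNames(rep(c("control", "LPS"),
                                           c(length(ctl), length(trt))),
                                       colnames(counts)))
    psi_table(ev, ct, count_threshold = 0)
  }
  # identical groups: delta 0, untested at the default gate
  same <- ttest_diff(mk_psi(c(40, 42, 41), c(40, 42, 41)), treated = "LPS")
  expect_true(all(is.na(same$p_raw)))
  expect_equal(same$delta_psi[same$inclusion], 0)
  # complete separation: delta 80, p ~ 0
  sep <- ttest_diff(mk_psi(c(10, 10, 10), c(90, 90, 90)), treated = "LPS")
  expect_equal(sep$delta_psi[sep$inclusion], 80)
  expect_lt(sep$p_raw[sep$inclusion], 1e-6)
  # one group entirely missing: untested, not fatal
  miss <- mk_psi(c(20, 22, 21), c(80, 81, 79))
  miss$psi[, 4:6] <- NA
  expect_true(all(is.na(ttest_diff(miss, treated = "LPS")$p_raw)))
})

test_that("DM expression filters exclude events with recorded reasons", {
  ann <- make_annotation(
    list(gene = "g", tx = "t1", strand = "+",
         exons = ex(0, 200, 5000, 5200)),
    list(gene = "g", tx = "t2", strand = "+",
         exons = ex(1000, 1200, 5000, 5200)))
  ev <- build_events(ann)
  # expressed at >= 10 in only 5 of 6 samples: excluded under 6-sample rule
  m <- matrix(c(50, 50, 50, 50, 50, 4,
                50, 50, 50, 50, 50, 4), nrow = 2, byrow = TRUE,
              dimnames = list(ev$row_id, paste0("s", 1:6)))
  ct <- count_table(m, setNames(rep(c("control", "LPS"), each = 3),
                                paste0("s", 1:6)))
  res <- dm_lrt(ev, ct, min_samps_gene_expr = 6, min_gene_expr = 10)
  expect_equal(nrow(res), 0)
  expect_equal(attr(res, "excluded")$reason, "min_samps_gene_expr")
  # relaxing to 5 samples admits it
  res5 <- dm_lrt(ev, ct, min_samps_gene_expr = 5, min_gene_expr = 10)
  expect_equal(nrow(res5), 2)
})

test_that("both test routes agree on the sign of delta PSI", {
  toy <- shared_toy()
  psi <- psi_table(toy$events, toy$counts)
  rt <- ttest_diff(psi, treated = "LPS", delta_thresh = 0)
  rd <- dm_lrt(toy$events, toy$counts, treated = "LPS")
  key <- paste(rt$event_id, rt$candidate)
  kd <- paste(rd$event_id, rd$candidate)
  shared <- intersect(key[!is.na(rt$delta_psi)], kd[!is.na(rd$delta_psi)])
  a <- rt$delta_psi[match(shared, key)]
  b <- rd$delta_psi[match(shared, kd)]
  big <- abs(a) > 2 | abs(b) > 2   # identical signs up to noise near zero
  expect_true(all(sign(a[big]) == sign(b[big])))
})

test_that("significance filtering applies both thresholds and drops novel IR", {
  res <- data.frame(event_id = sprintf("e%d", 1:4),
                    event_type = c("AFE", "AFE", "IR", "IR"),
                    novelty = c("K", "K", "N", "K"),
                    gene_id = sprintf("g%d", 1:4),
                    chrom = "chr1", strand = "+", candidate = 1,
                    inclusion = TRUE, exon_start = 0, exon_end = 1,
                    mean_psi_control = 50, mean_psi_treated = 60,
                    delta_psi = c(12, 9, 50, 50),
                    p_raw = c(0.01, 0.01, 0.001, 0.001),
                    p_adj = c(0.2, 0.2, 0.01, 0.01),
                    test = "ttest", significant = NA)
  kept <- significant_events(res, alpha = 0.25, delta = 10)
  expect_setequal(kept$event_id, c("e1", "e4"))  # e2 fails delta, e3 is (IR, N)
  expect_true(all(kept$significant))
  strict <- significant_events(res, alpha = 0.05, delta = 10)
  expect_setequal(strict$event_id, "e4")
})

test_that("union and conserved gene sets follow set algebra", {
  mk <- function(types, genes) {
    data.frame(event_type = types, gene_id = genes)
  }
  u <- union_genes(mk(c("AFE", "AFE"), c("a", "b")), mk("AFE", "c"))
  expect_equal(u$AFE, c("a", "b", "c"))
  expect_equal(union_genes(mk("AFE", "a"), mk("AFE", "a"))$AFE, "a")
  toy <- shared_toy()
  psi <- psi_table(toy$events, toy$counts)
  sig_t <- significant_events(ttest_diff(psi, treated = "LPS"))
  sig_d <- significant_events(dm_lrt(toy$events, toy$counts, treated = "LPS"))
  u2 <- union_genes(sig_t, sig_d)
  for (ty in names(u2)) {
    expect_true(all(sig_t$gene_id[sig_t$event_type == ty] %in% u2[[ty]]))
    expect_lte(length(u2[[ty]]),
               length(unique(c(sig_t$gene_id[sig_t$event_type == ty],
                               sig_d$gene_id[sig_d$event_type == ty]))))
  }

  sets <- list(mouse = list(AFE = c("Aim2", "Ncoa7"), IR = "Foo"),
               human = list(AFE = c("AIM2", "WARS")))
  cons <- conserved_genes(sets)
  expect_equal(cons$AFE, "Aim2")
  expect_equal(cons$IR, character(0))
  # planted shared genes recovered exactly
  sets2 <- list(a = list(AFE = sprintf("g%02d", 1:20)),
                b = list(AFE = sprintf("G%02d", 6:16)))
  expect_equal(conserved_genes(sets2)$AFE, sprintf("g%02d", 6:16))
})

test_that("ranking composition restricts, sorts and takes ceilings", {
  res <- data.frame(event_id = sprintf("e%02d", 1:20),
                    event_type = rep(c("AFE", "CASSETTE"), each = 10),
                    novelty = "K", gene_id = sprintf("g%02d", 1:20),
                    chrom = "chr1", strand = "+", candidate = 1,
                    inclusion = TRUE, exon_start = 0, exon_end = 1,
                    mean_psi_control = 40, mean_psi_treated = 60,
                    delta_psi = 20, p_raw = (1:20) / 100, p_adj = NA,
                    test = "ttest", significant = NA)
  rc <- ranking_composition(res, percents = 5)
  expect_equal(sum(rc$count), 1)        # ceiling(0.05 * 20) = 1
  expect_equal(rc$event_type, "AFE")    # the single best-ranked event
  # all one type stays one type at every percent
  res$event_type <- "AFE"
  rc2 <- ranking_composition(res)
  expect_true(all(rc2$event_type == "AFE"))
  expect_equal(rc2$count, ceiling(c(5, 10, 15, 20, 25) / 100 * 20))
  # |delta| < 10 rows are ignored entirely
  res$delta_psi[1:10] <- 5
  rc3 <- ranking_composition(res, percents = 100)
  expect_equal(sum(rc3$count), 10)
})
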