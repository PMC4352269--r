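test_that("a single perfect hit gives f* = 0 and score 100", {
  tr <- source_transcript("t1", "t1", "chr1", "+",
                          data.frame(start = 100, end = 200))
  st <- build_stages(tr, make_hit(1, 3000, 3100))
  res <- solve_stages(st, tr)
  expect_true(res$feasible)
  expect_identical(res$f_star, 0)
  expect_identical(res$score, 100)
})

test_that("an empty stage is skipped at exactly the K penalty", {
  tr <- tiny_transcript()
  hits <- bind_hits(make_hit(1, 100, 200), make_hit(3, 900, 1000))
  res <- solve_stages(build_stages(tr, hits), tr)
  expect_true(res$feasible)
  expect_identical(res$states[2], 0L)
  expect_identical(res$f_star, 0.95)
  expect_equal(res$score, (1 - 0.95 / 3) * 100)
})

test_that("score normalization matches (1 - f*/N) * 100", {
  expect_identical(normalize_score(0, 5), 100)
  expect_identical(normalize_score(4, 4), 0)
  expect_identical(normalize_score(0.2 * 5, 5), 80)
})

test_that("solver equals the exhaustive oracle on random small instances", {
  set.seed(1234)
  n_nontrivial <- 0
  for (k in 1:120) {
    case <- random_dp_case()
    dp <- solve_stages(case$stages, case$transcript)
    bf <- brute_force_solve(case$stages, case$transcript)
    expect_identical(dp$f_star, bf$f_star)
    expect_identical(dp$states, bf$states)
    expect_identical(dp$feasible, bf$feasible)
    if (dp$feasible && sum(vapply(case$stages, nrow, 0L)) > 2) {
      n_nontrivial <- n_nontrivial + 1
    }
  }
  expect_gt(n_nontrivial, 30)  # the suite exercises real instances
})

test_that("Bellman consistency: the returned path re-scores to f*", {
  set.seed(99)
  for (k in 1:25) {
    case <- random_dp_case()
    dp <- solve_stages(case$stages, case$transcript)
    expect_identical(annolift:::path_cost(dp$states, case$stages,
                                          case$transcript, cost_params()),
                     dp$f_star)
    if (dp$feasible) {
      expect_gte(dp$score, 0)
      expect_lte(dp$score, 100)
    }
  }
})

test_that("adding a dominated hit never changes f*", {
  set.seed(555)
  for (k in 1:20) {
    case <- random_dp_case()
    ms <- vapply(case$stages, nrow, 0L)
    if (!any(ms > 0)) next
    dp0 <- solve_stages(case$stages, case$transcript)
    i <- which(ms > 0)[1]
    dom <- case$stages[[i]][1, , drop = FALSE]
    dom$evalue <- dom$evalue + 1
    dom$input_order <- max(unlist(lapply(case$stages, `[[`, "input_order")), 0) + 1L
    st2 <- case$stages
    st2[[i]] <- rbind(st2[[i]], dom)
    st2[[i]] <- st2[[i]][order(st2[[i]]$evalue, st2[[i]]$target_start,
                               st2[[i]]$input_order), , drop = FALSE]
    dp1 <- solve_stages(st2, case$transcript)
    expect_identical(dp1$f_star, dp0$f_star)
  }
})

test_that("the all-skip path is infeasible and a hopeless single hit is dropped", {
  tr <- tiny_transcript()
  res <- solve_stages(build_stages(tr, annolift:::empty_hits()), tr)
  expect_false(res$feasible)
  expect_identical(res$states, rep(0L, 3))
  expect_identical(res$f_star, 3 * 0.95)
  # single-exon transcript with a terrible hit: terminal cost 0.99 > K
  tr1 <- source_transcript("t1", "t1", "chr1", "+",
                           data.frame(start = 0, end = 100))
  weak <- make_hit(1, 50, 51, align_length = 1, exon_length = 100)
  res1 <- solve_stages(build_stages(tr1, weak), tr1)
  expect_false(res1$feasible)
})

test_that("fixed_chrom excludes hits on other chromosomes", {
  tr <- tiny_transcript()
  hits <- bind_hits(
    make_hit(1, 100, 200), make_hit(2, 400, 500), make_hit(3, 900, 1000),
    make_hit(1, 100, 200, target_chrom = "chr2"),
    make_hit(2, 400, 500, target_chrom = "chr2"),
    make_hit(3, 900, 1000, target_chrom = "chr2"))
  st <- build_stages(tr, hits)
  res <- solve_stages(st, tr, fixed_chrom = "chr2")
  expect_true(all(res$hits$target_chrom == "chr2"))
  bf <- brute_force_solve(st, tr, fixed_chrom = "chr2")
  expect_identical(res$f_star, bf$f_star)
})

test_that("brute force refuses oversized instances", {
  tr <- source_transcript("t1", "t1", "chr1", "+",
                          data.frame(start = (0:9) * 1000,
                                     end = (0:9) * 1000 + 100))
  rows <- do.call(bind_hits, lapply(rep(1:10, each = 6), function(i) {
    make_hit(i, sample(1:5e4, 1), sample(50001:50100, 1))
  }))
  rows$target_end <- rows$target_start + 100L
  st <- build_stages(tr, rows)
  expect_error(brute_force_solve(st, tr), "guard")
})

test_that("assembly reproduces coordinates, records skips and carries strand", {
  tr <- tiny_transcript()
  res <- solve_stages(build_stages(tr, perfect_hits(tr)), tr)
  ann <- assemble_annotation(res, tr)
  expect_equal(ann$blocks, tr$exons)
  expect_identical(ann$strand, "+")
  expect_identical(ann$score, 100)
  expect_length(ann$skipped_exons, 0)
  # skip on a 3-exon transcript -> 2 blocks, skipped index recorded
  hits <- bind_hits(make_hit(1, 100, 200), make_hit(3, 900, 1000))
  res2 <- solve_stages(build_stages(tr, hits), tr)
  ann2 <- assemble_annotation(res2, tr)
  expect_equal(nrow(ann2$blocks), 2)
  expect_identical(ann2$skipped_exons, 2L)
  # "-" hits for a "+" source -> annotation strand "-"
  hm <- bind_hits(make_hit(1, 2000, 2100, strand = "-"),
                  make_hit(2, 1700, 1800, strand = "-"),
                  make_hit(3, 1000, 1100, strand = "-"))
  res3 <- solve_stages(build_stages(tr, hm), tr)
  ann3 <- assemble_annotation(res3, tr)
  expect_true(res3$feasible)
  expect_identical(ann3$strand, "-")
  expect_equal(ann3$blocks$start, c(1000, 1700, 2000))
  # infeasible result -> NULL
  resx <- solve_stages(build_stages(tr, annolift:::empty_hits()), tr)
  expect_null(assemble_annotation(resx, tr))
})

test_that("minus-strand source transcripts solve equivalently", {
  trm <- tiny_transcript(strand = "-")
  res <- solve_stages(build_stages(trm, perfect_hits(trm)), trm)
  expect_identical(res$f_star, 0)
  ann <- assemble_annotation(res, trm)
  expect_equal(ann$blocks, trm$exons)
  expect_identical(ann$strand, "-")
})
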