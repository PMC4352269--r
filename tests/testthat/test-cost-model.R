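test_that("chromosome and strand feasibility terms are 0 or Inf", {
  a <- make_hit(1, 0, 100)
  b <- make_hit(2, 500, 600)
  b_chr7 <- make_hit(2, 500, 600, target_chrom = "chr7")
  b_minus <- make_hit(2, 500, 600, strand = "-")
  expect_identical(chr_dist(a, b), 0)
  expect_identical(chr_dist(a, b_chr7), Inf)
  expect_identical(chr_dist(a, a), 0)
  expect_identical(strand_cost(a, b), 0)
  expect_identical(strand_cost(a, b_minus), Inf)
  expect_identical(strand_cost(b_minus, b_minus), 0)
})

test_that("alignment quality follows length fraction times exp(-E)", {
  expect_identical(align_quality(make_hit(1, 0, 100, evalue = 0)), 1)
  expect_identical(align_quality(make_hit(1, 0, 100, evalue = 0,
                                          align_length = 50)), 0.5)
  expect_equal(align_quality(make_hit(1, 0, 100, evalue = 2)), exp(-2))
  # clamped at 1 when gapped alignments exceed the exon length
  gapped <- make_hit(1, 0, 100, evalue = 0, align_length = 120)
  expect_identical(align_quality(gapped), 1)
  expect_gt(align_quality(gapped, cost_params(clamp_align = FALSE)), 1)
  bad <- make_hit(1, 0, 100)
  bad$exon_length <- 0L
  expect_error(align_quality(bad), "exon_length")
})

test_that("distance ratio handles equal, unequal and degenerate distances", {
  expect_identical(rela(1000, 1000), 1)
  expect_identical(rela(500, 1000), 0.5)
  expect_identical(rela(0, 0), 1)
  expect_identical(rela(0, 100), 0)
  expect_identical(rela(100, 0), 0)
  expect_error(rela(-5, 10), "absolute")
})

test_that("align_rela combines quality and spacing; overlaps are vetoed", {
  a <- make_hit(1, 100, 200)
  b <- make_hit(2, 1200, 1300)
  # perfect quality, matching distances -> 0
  expect_identical(align_rela(a, b, dist_source = 1000), 0)
  # quality 0.2, rela 1 -> poor product, cost 0.8
  a02 <- make_hit(1, 100, 200, align_length = 20, evalue = 0)
  expect_identical(align_rela(a02, b, dist_source = 1000), 0.8)
  # quality 0 -> worst case 1
  a0 <- make_hit(1, 100, 200, evalue = 1e6)
  expect_identical(align_rela(a0, b, dist_source = 1000), 1)
  # gross overlap (> 50% of either hit) -> Inf
  b_over <- make_hit(2, 120, 220)
  expect_identical(align_rela(a, b_over, dist_source = 1000), Inf)
  # mild overlap uses |distance|
  b_mild <- make_hit(2, 180, 280)
  expect_identical(align_rela(a, b_mild, dist_source = 20), 0)
})

test_that("one-step cost covers skip, feasibility, perfect and terminal cases", {
  tr <- tiny_transcript()  # exons [100,200) [400,500) [900,1000)
  params <- cost_params()
  h1 <- make_hit(1, 100, 200)
  h2 <- make_hit(2, 400, 500)
  expect_identical(one_step_cost(NULL, h2, 1, 2, tr, params), 0.95)
  expect_identical(one_step_cost(h1, make_hit(2, 400, 500, target_chrom = "chr9"),
                                 1, 2, tr, params), Inf)
  # same chrom/strand, quality 1, matching intron -> 0
  expect_identical(one_step_cost(h1, h2, 1, 2, tr, params), 0)
  # terminal rule: 1 - align_quality
  h_weak <- make_hit(3, 900, 1000, align_length = 60, evalue = 0)
  expect_identical(one_step_cost(h_weak, NULL, 3, 4, tr, params), 0.4)
})

test_that("bridged skips use the summed source span; unit policy uses rela 1", {
  tr <- tiny_transcript()  # exon1 ends 200, exon3 starts 900 -> bridge span 700
  h1 <- make_hit(1, 100, 200)
  h3_bridge <- make_hit(3, 900, 1000)   # target gap 700 -> rela 1
  h3_far <- make_hit(3, 1250, 1350)     # target gap 1050 -> rela 700/1050
  expect_identical(one_step_cost(h1, h3_bridge, 1, 3, tr, cost_params()), 0)
  expect_equal(one_step_cost(h1, h3_far, 1, 3, tr, cost_params()),
               1 - 700 / 1050)
  expect_identical(one_step_cost(h1, h3_far, 1, 3, tr,
                                 cost_params(skip_rela_policy = "unit")), 0)
})

test_that("minus-strand chains measure the target gap in descending order", {
  tr <- tiny_transcript()  # "+" source; "-" hits = inverted transfer
  h1 <- make_hit(1, 2000, 2100, strand = "-")
  h2 <- make_hit(2, 1700, 1800, strand = "-")  # gap = 2000 - 1800 = 200 = intron
  expect_identical(target_gap(h1, h2, "+"), 200L)
  expect_identical(one_step_cost(h1, h2, 1, 2, tr, cost_params()), 0)
})

test_that("cost is monotone in E-value and aligned length", {
  tr <- tiny_transcript()
  b <- make_hit(2, 1200, 1300)
  evs <- c(0, 1e-5, 0.1, 1, 5, 50)
  costs <- vapply(evs, function(e) {
    one_step_cost(make_hit(1, 100, 200, evalue = e), b, 1, 2, tr, cost_params())
  }, 0)
  expect_true(all(diff(costs) >= 0))
  alens <- c(10, 40, 70, 100)
  costs <- vapply(alens, function(al) {
    one_step_cost(make_hit(1, 100, 200, align_length = al), b, 1, 2, tr,
                  cost_params())
  }, 0)
  expect_true(all(diff(costs) <= 0))
})

test_that("finite one-step costs lie in [0, 1] over random inputs", {
  set.seed(7)
  tr <- tiny_transcript()
  for (k in 1:200) {
    s <- sample(1:3000, 1)
    s2 <- sample(1:3000, 1)
    a <- make_hit(1, s, s + sample(30:150, 1),
                  evalue = stats::runif(1, 0, 3),
                  align_length = sample(10:150, 1), exon_length = 100)
    b <- make_hit(2, s2, s2 + sample(30:150, 1))
    d <- one_step_cost(a, b, 1, 2, tr, cost_params())
    expect_true(is.infinite(d) || (d >= 0 && d <= 1))
  }
})
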