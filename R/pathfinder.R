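# Stage-wise shortest path over exon alignment stages.
#
# A path assigns one state per stage: an alignment hit or "skip". Cost
# attribution (one term per stage, so the normalized score spans [0,100]):
# skip -> K; retained hit followed by another retained hit -> feasibility
# terms + align/rela; last retained hit -> 1 - align_quality (terminal
# rule). Solver and brute-force oracle share path_cost() (one canonical
# floating-point fold) and cand_better() (one tie comparator), so their
# f* and chosen paths agree exactly.

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_hit <- function(stages, i, h) stages[[i]][h, , drop = FALSE]

# Canonical total cost of a state assignment (0 = skip), summed
# suffix-first with skipped runs added as count * K.
path_cost <- function(states, stages, transcript, params = cost_params()) {
  N <- length(states)
  retained <- which(states > 0L)
  if (!length(retained)) return(N * params$K)
  last <- retained[length(retained)]
  acc <- (N - last) * params$K +
    one_step_cost(stage_hit(stages, last, states[last]), NULL,
                  last, N + 1L, transcript, params)
  nr <- length(retained)
  if (nr > 1) {
    for (k in (nr - 1):1) {
      i <- retained[k]
      j <- retained[k + 1]
      step <- (j - i - 1) * params$K +
        one_step_cost(stage_hit(stages, i, states[i]),
                      stage_hit(stages, j, states[j]),
                      i, j, transcript, params)
      acc <- step + acc
    }
  }
  (retained[1] - 1) * params$K + acc
}

# Deterministic path preference: lower cost (tolerance tol), then fewer
# skips, then lexicographically smaller target_start sequence, then
# smaller input-order sequence.
cand_better <- function(a, b, tol = 1e-9) {
  if (is.null(b)) return(TRUE)
  if (a$cost < b$cost - tol) return(TRUE)
  if (a$cost > b$cost + tol) return(FALSE)
  if (a$nskips != b$nskips) return(a$nskips < b$nskips)
  n <- min(length(a$starts), length(b$starts))
  if (n > 0) {
    d <- which(a$starts[seq_len(n)] != b$starts[seq_len(n)])
    if (length(d)) return(a$starts[d[1]] < b$starts[d[1]])
    d <- which(a$idxs[seq_len(n)] != b$idxs[seq_len(n)])
    if (length(d)) return(a$idxs[d[1]] < b$idxs[d[1]])
  }
  FALSE
}

cand_stats <- function(states, stages) {
  retained <- which(states > 0L)
  list(nskips = length(states) - length(retained),
       starts = vapply(retained, function(i) stages[[i]]$target_start[states[i]], 0),
       idxs = vapply(retained, function(i) {
         s <- stages[[i]]
         if ("input_order" %in% names(s)) s$input_order[states[i]] else states[i]
       }, 0))
}

apply_fixed_chrom <- function(stages, fixed_chrom) {
  if (is.null(fixed_chrom)) return(stages)
  out <- lapply(stages, function(s) {
    s <- s[s$target_chrom == fixed_chrom, , drop = FALSE]
    rownames(s) <- NULL
    s
  })
  attributes(out) <- attributes(stages)
  out
}

#' Normalize a total path cost to a 0-100 score
#'
#' `(1 - f_star / N) * 100`; 100 is the optimum (every stage contributes
#' zero cost), 0 corresponds to a total cost of `N`.
#'
#' @param f_star minimal total path cost.
#' @param N number of stages (source exon count).
#' @return numeric score.
#' @export
normalize_score <- function(f_star, N) {
  (1 - f_star / N) * 100
}

dp_result_obj <- function(states, stages, transcript, f_star) {
  N <- length(states)
  retained <- which(states > 0L)
  feasible <- length(retained) > 0 && is.finite(f_star)
  hits <- NULL
  if (length(retained)) {
    hits <- do.call(rbind, lapply(retained, function(i) {
      cbind(stage = i, stages[[i]][states[i], , drop = FALSE])
    }))
    rownames(hits) <- NULL
  }
  structure(list(transcript_id = transcript$transcript_id,
                 states = states,
                 f_star = f_star,
                 score = normalize_score(f_star, N),
                 feasible = feasible,
                 skipped = which(states == 0L),
                 hits = hits),
            class = "dp_result")
}

#' @export
print.dp_result <- function(x, ...) {
  cat(sprintf("<dp_result %s f*=%.6g score=%.2f %s skips=%d>\n",
              x$transcript_id, x$f_star, x$score,
              if (x$feasible) "feasible" else "INFEASIBLE",
              length(x$skipped)))
  invisible(x)
}

#' Solve the stage-wise shortest path for one transcript
#'
#' Backward Bellman recursion over stages in ascending genomic exon order:
#' the value of choosing hit `h` at stage `i` is the minimal cost of any
#' suffix path starting there, built from transitions to the next retained
#' stage (intermediate skipped stages each charge `K`) or to the End
#' point. The all-skip assignment competes on cost but is marked
#' infeasible (it carries no coordinates to annotate). Ties are broken by
#' fewest skips, then leftmost target starts, then input order, so results
#' are deterministic.
#'
#' @param stages an `alignment_stages` object from [build_stages()].
#' @param transcript the corresponding `source_transcript`.
#' @param params a [cost_params()] object.
#' @param fixed_chrom optional target chromosome restriction: hits on
#'   other chromosomes are excluded before solving.
#' @return object of class `dp_result`: `states` (per-stage chosen hit
#'   row, 0 = skip), `f_star`, `score`, `feasible`, `skipped`, `hits`.
#' @export
solve_stages <- function(stages, transcript, params = cost_params(),
                         fixed_chrom = NULL) {
  N <- attr(stages, "N") %||% length(stages)
  if (N != transcript$N) stop("stage count does not match transcript exon count")
  st <- apply_fixed_chrom(stages, fixed_chrom)
  K <- params$K
  best <- vector("list", N)
  for (i in N:1) {
    m <- nrow(st[[i]])
    best[[i]] <- vector("list", m)
    for (h in seq_len(m)) {
      a <- stage_hit(st, i, h)
      idx_a <- if ("input_order" %in% names(a)) a$input_order else h
      cand <- list(
        cost = (N - i) * K + one_step_cost(a, NULL, i, N + 1L, transcript, params),
        nskips = N - i,
        starts = a$target_start,
        idxs = idx_a,
        states = c(h, rep(0L, N - i)))
      if (i < N) {
        for (j in (i + 1):N) {
          for (h2 in seq_len(nrow(st[[j]]))) {
            suf <- best[[j]][[h2]]
            core <- one_step_cost(a, stage_hit(st, j, h2), i, j, transcript, params)
            if (is.infinite(core)) next
            step <- (j - i - 1) * K + core
            cand2 <- list(cost = step + suf$cost,
                          nskips = (j - i - 1) + suf$nskips,
                          starts = c(a$target_start, suf$starts),
                          idxs = c(idx_a, suf$idxs),
                          states = c(h, rep(0L, j - i - 1), suf$states))
            if (cand_better(cand2, cand)) cand <- cand2
          }
        }
      }
      best[[i]][[h]] <- cand
    }
  }
  top <- list(cost = N * K, nskips = N, starts = numeric(0), idxs = numeric(0),
              states = rep(0L, N))
  for (k in seq_len(N)) {
    for (h in seq_len(nrow(st[[k]]))) {
      c0 <- best[[k]][[h]]
      cand <- list(cost = (k - 1) * K + c0$cost,
                   nskips = (k - 1) + c0$nskips,
                   starts = c0$starts, idxs = c0$idxs,
                   states = c(rep(0L, k - 1), c0$states))
      if (cand_better(cand, top)) top <- cand
    }
  }
  dp_result_obj(top$states, st, transcript, top$cost)
}

#' Exhaustive-enumeration oracle for the shortest-path solver
#'
#' Enumerates every state assignment (hit or skip per stage), scores each
#' with the same canonical cost fold as [solve_stages()], and returns the
#' minimum under the same tie rules. Intended as an independent test
#' oracle for small instances.
#'
#' @inheritParams solve_stages
#' @param guard refuse instances with more than this many combinations.
#' @return a `dp_result`, comparable field-by-field with [solve_stages()].
#' @export
brute_force_solve <- function(stages, transcript, params = cost_params(),
                              fixed_chrom = NULL, guard = 1e6) {
  N <- attr(stages, "N") %||% length(stages)
  if (N != transcript$N) stop("stage count does not match transcript exon count")
  st <- apply_fixed_chrom(stages, fixed_chrom)
  ms <- vapply(st, nrow, 0L)
  if (prod(ms + 1) > guard) {
    stop(sprintf("brute force refused: %.3g combinations exceed guard %g",
                 prod(ms + 1), guard))
  }
  grid <- expand.grid(lapply(ms, function(m) 0:m), KEEP.OUT.ATTRS = FALSE)
  top <- NULL
  for (r in seq_len(nrow(grid))) {
    states <- as.integer(unlist(grid[r, ], use.names = FALSE))
    cost <- path_cost(states, st, transcript, params)
    if (is.infinite(cost)) next
    stt <- cand_stats(states, st)
    cand <- list(cost = cost, nskips = stt$nskips, starts = stt$starts,
                 idxs = stt$idxs, states = states)
    if (cand_better(cand, top)) top <- cand
  }
  dp_result_obj(top$states, st, transcript, top$cost)
}

#' Assemble the winning path into a candidate annotation
#'
#' Exon blocks are the target intervals of the retained hits, sorted in
#' ascending coordinates; chromosome and strand come from the retained
#' hits (identical across the path by construction — exon queries are
#' extracted transcript-oriented, so the hit strand already composes the
#' source strand with the target orientation). Slight overlaps between
#' consecutive retained hits (tolerated by the cost model up to
#' `max_overlap_frac`) are trimmed on the downstream block so the output
#' blocks are disjoint.
#'
#' @param result a feasible `dp_result`.
#' @param transcript the matching `source_transcript`.
#' @return a [candidate_annotation()], or `NULL` when `result` is
#'   infeasible (transcript dropped).
#' @export
assemble_annotation <- function(result, transcript) {
  if (!result$feasible) return(NULL)
  hits <- result$hits
  chrom <- unique(hits$target_chrom)
  strand <- unique(hits$strand)
  stopifnot(length(chrom) == 1, length(strand) == 1)
  blocks <- data.frame(start = hits$target_start, end = hits$target_end)
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  if (nrow(blocks) > 1) {
    for (k in 2:nrow(blocks)) {
      if (blocks$start[k] < blocks$end[k - 1]) blocks$start[k] <- blocks$end[k - 1]
    }
  }
  candidate_annotation(
    transcript_id = transcript$transcript_id,
    source_transcript_id = transcript$transcript_id,
    chrom = chrom, strand = strand, blocks = blocks,
    score = min(max(result$score, 0), 100),
    canonical_flag = "canonical",
    skipped_exons = result$skipped)
}
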