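# The three-phase per-cluster search. All phases accept only strictly
# improving moves under the lexicographic objective, which guarantees
# termination (objective ascent on a finite lattice) and determinism (fixed
# enumeration orders, no randomness).

now_s <- function() as.numeric(Sys.time())

# lexicographic combination successor: c is an increasing index vector into
# seq_len(n); returns NULL after the last combination
next_comb <- function(c, n) {
  k <- length(c)
  i <- k
  while (i >= 1L && c[i] == n - k + i) i <- i - 1L
  if (i == 0L) return(NULL)
  c[i] <- c[i] + 1L
  if (i < k) c[(i + 1L):k] <- c[i] + seq_len(k - i)
  c
}

# all subsets of v, smallest first, lexicographic within a size; when v is
# large, only small subsets plus v itself are enumerated (heuristic phases)
subsets_upto <- function(v, full_limit = 10L) {
  n <- length(v)
  if (n == 0) return(list(integer()))
  max_sz <- if (n <= full_limit) n else 2L
  out <- list(integer())
  for (sz in seq_len(max_sz)) {
    cmb <- utils::combn(v, sz, simplify = FALSE)
    out <- c(out, cmb)
  }
  if (n > full_limit) out <- c(out, list(v))
  out
}

# ---- phase 1: greedy near-optimal start ------------------------------------
#
# Obligates are seeded first (conflicting obligates resolved by objective
# comparison, earlier-ranked kept on ties). The greedy fill then considers
# only tag SNPs with no conflict edge (and single-bead tags in Infinium
# mode), repeatedly picking the candidate tagging the most bins that still
# need tags (NPtag), breaking ties by the ranked pool order, until every bin
# has reached its cap or its maximum genotyping probability.
phase1_cc <- function(cc) {
  sel <- logical(cc$n)
  dropped <- integer()
  for (o in which(cc$obligate)) {
    cand <- sel
    cand[o] <- TRUE
    if (!is.null(cl_obj(cc, cand))) {
      sel <- cand
      next
    }
    # o is blocked by earlier obligates (proximity or bin cap); compare the
    # two alternatives and keep the better, ties keep the incumbent
    blockers <- intersect(which(sel), cc$adj[[o]])
    for (b in cc$bins_of[[o]]) {
      cb <- cc$cand[[b]]
      if (sum(sel[cb]) >= cc$max_tags[b]) {
        blockers <- c(blockers, cb[sel[cb]])
      }
    }
    blockers <- sort(unique(blockers))
    alt <- sel
    alt[blockers] <- FALSE
    alt[o] <- TRUE
    alt_obj <- cl_obj(cc, alt)
    if (!is.null(alt_obj) && obj_better(alt_obj, cl_obj(cc, sel))) {
      sel <- alt
      dropped <- c(dropped, blockers)
    } else {
      dropped <- c(dropped, o)
    }
  }
  dropped <- setdiff(dropped, which(sel))

  conflicted <- lengths(cc$adj) > 0L
  restricted <- !conflicted & (!cc$infinium | cc$beads == 1L) & !cc$obligate
  counts <- cand_counts(cc, sel)
  repeat {
    needy <- bin_needs(cc, sel, counts)
    if (!any(needy)) break
    open <- which(restricted & !sel)
    if (length(open) == 0) break
    np <- vapply(open, function(s) sum(needy[cc$bins_of[[s]]]), integer(1))
    feas <- vapply(open, function(s) {
      bs <- cc$bins_of[[s]]
      all(counts[bs] < cc$max_tags[bs])
    }, logical(1))
    ok <- np > 0L & feas
    if (!any(ok)) break
    open <- open[ok]
    np <- np[ok]
    pick <- open[order(-np, open)][1]
    sel[pick] <- TRUE
    counts[cc$bins_of[[pick]]] <- counts[cc$bins_of[[pick]]] + 1L
  }
  list(sel = sel, dropped_obligates = dropped)
}

# bins that still need tags: below cap, below the probability threshold, and
# not covered by an existing genotype
bin_needs <- function(cc, sel, counts) {
  nb <- length(cc$cand)
  needy <- logical(nb)
  for (b in seq_len(nb)) {
    if (cc$covered[b] || counts[b] >= cc$max_tags[b]) next
    cb <- cc$cand[[b]]
    scb <- cb[sel[cb]]
    Pb <- if (length(scb)) 1 - prod(1 - cc$p[scb]) else 0
    needy[b] <- Pb < cc$cap - 1e-12
  }
  needy
}

# ---- phase 2: swap in conflict-involved / two-bead tags --------------------
#
# Tags phase 1 never considered (members of conflicting pairs; two-bead tags
# in Infinium mode) are tried in ranked order, each together with removal
# subsets drawn from the selected tags it interacts with (conflict partners
# or bin mates), accepting strictly improving moves until a fixed point.
phase2_cc <- function(cc, sel) {
  conflicted <- lengths(cc$adj) > 0L
  skipped <- which(conflicted | (cc$infinium & cc$beads == 2L))
  cur <- sel
  cur_obj <- cl_obj(cc, cur)
  if (length(skipped)) {
    repeat {
      improved <- FALSE
      for (t in skipped) {
        if (cur[t]) next
        D <- sort(intersect(which(cur),
                            unique(c(cc$adj[[t]], cc$mates[[t]]))))
        for (R in subsets_upto(D)) {
          cand <- cur
          cand[R] <- FALSE
          cand[t] <- TRUE
          o <- cl_obj(cc, cand)
          if (obj_better(o, cur_obj)) {
            cur <- cand
            cur_obj <- o
            improved <- TRUE
            break
          }
        }
      }
      if (!improved) break
    }
  }
  list(sel = cur, obj = cur_obj)
}

# ---- phase 3: time-budgeted exhaustive swap --------------------------------
#
# Systematic replacement of zero or more selected tags (out-subset of size at
# most 20) with zero or more of the remaining pool, enumerated in ranked
# order, restarting from the new baseline on every improvement. Stops when
# the enumeration completes with no improving move (exhausted = TRUE) or when
# the wall-clock deadline passes.
phase3_cc <- function(cc, sel, deadline) {
  cur <- sel
  cur_obj <- cl_obj(cc, cur)
  evals <- 0L
  repeat {
    S <- which(cur)
    U <- which(!cur)
    found <- FALSE
    timed_out <- FALSE
    for (osz in 0:min(20L, length(S))) {
      oc <- if (osz > 0) seq_len(osz) else integer()
      repeat {
        R <- if (osz > 0) S[oc] else integer()
        for (asz in 0:length(U)) {
          ac <- if (asz > 0) seq_len(asz) else integer()
          repeat {
            if (osz + asz > 0L) {
              evals <- evals + 1L
              if (evals %% 64L == 0L && now_s() > deadline) {
                timed_out <- TRUE
                break
              }
              A <- if (asz > 0) U[ac] else integer()
              cand <- cur
              cand[R] <- FALSE
              cand[A] <- TRUE
              o <- cl_obj(cc, cand)
              if (obj_better(o, cur_obj)) {
                cur <- cand
                cur_obj <- o
                found <- TRUE
                break
              }
            }
            if (asz == 0L) break
            ac <- next_comb(ac, length(U))
            if (is.null(ac)) break
          }
          if (found || timed_out) break
        }
        if (found || timed_out || osz == 0L) break
        oc <- next_comb(oc, length(S))
        if (is.null(oc)) break
      }
      if (found || timed_out) break
    }
    if (timed_out) {
      return(list(sel = cur, obj = cur_obj, exhausted = FALSE,
                  timed_out = TRUE))
    }
    if (!found) {
      return(list(sel = cur, obj = cur_obj, exhausted = TRUE,
                  timed_out = FALSE))
    }
  }
}

# ---- approximate fallback ---------------------------------------------------
#
# Single-in / multi-out swaps: each unselected tag in ranked order is tried
# with removal subsets drawn from the selected tags it interacts with, plus
# pure removals; passes repeat until no move improves. Polynomial per pass,
# used when the pool is too large for the exhaustive swap (more than 31 tags)
# or when the deadline truncated it.
approx_cc <- function(cc, sel) {
  cur <- sel
  cur_obj <- cl_obj(cc, cur)
  repeat {
    improved <- FALSE
    for (s in which(cur)) {
      cand <- cur
      cand[s] <- FALSE
      o <- cl_obj(cc, cand)
      if (obj_better(o, cur_obj)) {
        cur <- cand
        cur_obj <- o
        improved <- TRUE
      }
    }
    for (t in seq_len(cc$n)) {
      if (cur[t]) next
      D <- sort(intersect(which(cur), unique(c(cc$adj[[t]], cc$mates[[t]]))))
      for (R in subsets_upto(D)) {
        cand <- cur
        cand[R] <- FALSE
        cand[t] <- TRUE
        o <- cl_obj(cc, cand)
        if (obj_better(o, cur_obj)) {
          cur <- cand
          cur_obj <- o
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) break
  }
  list(sel = cur, obj = cur_obj)
}

# ---- per-cluster driver -----------------------------------------------------

optimize_cluster <- function(cc, config) {
  t0 <- now_s()
  p1 <- phase1_cc(cc)
  p2 <- phase2_cc(cc, p1$sel)
  sel <- p2$sel
  obj <- p2$obj
  phase <- "phase2"
  exhausted <- FALSE
  approx_used <- FALSE
  if (config$time_limit_s > 0) {
    if (config$force_approximate || cc$n > 31L) {
      r <- approx_cc(cc, sel)
      sel <- r$sel
      obj <- r$obj
      phase <- "approximate"
      approx_used <- TRUE
    } else {
      r3 <- phase3_cc(cc, sel, t0 + config$time_limit_s)
      sel <- r3$sel
      obj <- r3$obj
      if (r3$exhausted) {
        phase <- "phase3"
        exhausted <- TRUE
      } else {
        r <- approx_cc(cc, sel)
        sel <- r$sel
        obj <- r$obj
        phase <- "approximate"
        approx_used <- TRUE
      }
    }
  }
  list(sel = sel, obj = obj, phase = phase, exhausted = exhausted,
       approx_used = approx_used, elapsed = now_s() - t0,
       dropped_obligates = p1$dropped_obligates)
}
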