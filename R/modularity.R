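#' Barber bipartite modularity of a given partition
#'
#' Q = (1/F) * sum_ij (A_ij - k_i d_j / F) [g_i = g_j], where F is the total
#' link count, k and d the plant and pollinator degrees, and g the shared
#' module labels. Plants and pollinators share module ids.
#'
#' @param M a `bipartite_matrix` or 0/1 matrix.
#' @param assignment named vector mapping every plant and pollinator label
#'   to a module id (any atomic labels), or an unnamed vector over
#'   `c(plants, pollinators)` in matrix order.
#' @return Numeric modularity, at most 1.
#' @export
barber_q <- function(M, assignment) {
  A <- if (inherits(M, "bipartite_matrix")) M$cells else as.matrix(M)
  P <- nrow(A); S <- P + ncol(A)
  sp <- c(rownames(A), colnames(A))
  if (!is.null(names(assignment))) {
    if (!all(sp %in% names(assignment))) {
      stop("assignment is missing species: ",
           paste(utils::head(setdiff(sp, names(assignment)), 5L),
                 collapse = ", "), call. = FALSE)
    }
    assignment <- assignment[sp]
  } else if (length(assignment) != S) {
    stop("unnamed assignment must have length P + A", call. = FALSE)
  }
  g <- as.integer(factor(assignment))
  .barber_q_impl(A, g[seq_len(P)], g[-seq_len(P)])
}

.barber_q_impl <- function(A, gp, ga) {
  F <- sum(A)
  k <- rowSums(A); d <- colSums(A)
  nm <- max(gp, ga)
  e <- Kp <- Ka <- numeric(nm)
  idx <- which(A == 1, arr.ind = TRUE)
  same <- gp[idx[, 1L]] == ga[idx[, 2L]]
  if (any(same)) {
    tab <- tabulate(gp[idx[same, 1L]], nbins = nm)
    e <- tab
  }
  Kp <- vapply(seq_len(nm), function(m) sum(k[gp == m]), numeric(1))
  Ka <- vapply(seq_len(nm), function(m) sum(d[ga == m]), numeric(1))
  sum(e) / F - sum(Kp * Ka) / F^2
}

#' Maximize Barber modularity by simulated annealing
#'
#' Searches partitions of the P + A species (plants and pollinators share
#' module ids) for high Barber modularity. Moves are single-species
#' reassignments (Metropolis acceptance exp(dQ/T)) plus one module-merge
#' and one module-split proposal per sweep; the temperature is initialised
#' so roughly half the sampled moves would be accepted, then cooled
#' geometrically. Each restart ends with a greedy refinement pass; the best
#' partition over restarts is returned, and is never worse than the trivial
#' one-module partition (Q = 0).
#'
#' @param M a `bipartite_matrix` or 0/1 matrix with dimnames.
#' @param n_restarts annealing restarts (default 10).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param cooling geometric cooling factor per sweep (default 0.995).
#' @param patience stop a restart after this many sweeps without
#'   improvement (default 200).
#' @param max_sweeps hard cap on sweeps per restart.
#' @return Object of class `module_partition`: list with `name`,
#'   `assignment` (named integer vector over all species), `Q`,
#'   `n_modules`, `trace` (best Q per restart), `seed`.
#' @export
optimize_modules <- function(M, n_restarts = 10L, seed = 1L,
                             cooling = 0.995, patience = 200L,
                             max_sweeps = 1500L) {
  A <- if (inherits(M, "bipartite_matrix")) M$cells else as.matrix(M)
  name <- if (inherits(M, "bipartite_matrix")) M$name else "matrix"
  if (is.null(rownames(A))) rownames(A) <- paste0("r", seq_len(nrow(A)))
  if (is.null(colnames(A))) colnames(A) <- paste0("c", seq_len(ncol(A)))
  if (!is.null(seed)) set.seed(seed)
  P <- nrow(A); Ap <- ncol(A); S <- P + Ap
  F <- sum(A)
  deg <- c(rowSums(A), colSums(A))
  # neighbour lists in species numbering (plants 1..P, pollinators P+1..S)
  nbrs <- c(lapply(seq_len(P), function(i) P + which(A[i, ] == 1)),
            lapply(seq_len(Ap), function(j) which(A[, j] == 1)))
  is_plant <- c(rep(TRUE, P), rep(FALSE, Ap))

  q_of <- function(g) .barber_q_impl(A, as.integer(factor(g))[seq_len(P)],
                                     as.integer(factor(g))[-seq_len(P)])

  # opposite-guild degree mass of species s's target/source modules
  delta_single <- function(g, W_opp, s, to) {
    from <- g[s]
    if (from == to) return(0)
    nb <- nbrs[[s]]
    n_to <- sum(g[nb] == to); n_from <- sum(g[nb] == from)
    (n_to - n_from) / F -
      deg[s] * (W_opp[to] - W_opp[from]) / F^2
  }

  run_restart <- function(r) {
    g <- if (r == 1L) seq_len(S) else
      sample.int(max(2L, sample.int(max(2L, ceiling(S / 3L)), 1L)), S,
                 replace = TRUE)
    # module aggregates of opposite-guild degree: Wp (plants), Wa (polls)
    Wp <- vapply(seq_len(S), function(m) sum(deg[is_plant & g == m]),
                 numeric(1))
    Wa <- vapply(seq_len(S), function(m) sum(deg[!is_plant & g == m]),
                 numeric(1))
    Q <- q_of(g)
    # temperature calibrated to ~50% acceptance of median move
    dqs <- abs(vapply(seq_len(100L), function(i) {
      s <- sample.int(S, 1L); t <- sample.int(S, 1L)
      delta_single(g, if (is_plant[s]) Wa else Wp, s, t)
    }, numeric(1)))
    T <- max(mean(dqs), 1e-4) / log(2)
    best_g <- g; best_Q <- Q; stall <- 0L; sweep <- 0L
    while (sweep < max_sweeps && stall < patience && T > 1e-7) {
      sweep <- sweep + 1L
      for (it in seq_len(S)) {
        s <- sample.int(S, 1L); to <- sample.int(S, 1L)
        W_opp <- if (is_plant[s]) Wa else Wp
        dq <- delta_single(g, W_opp, s, to)
        if (dq > 0 || stats::runif(1) < exp(dq / T)) {
          if (g[s] != to) {
            if (is_plant[s]) {
              Wp[g[s]] <- Wp[g[s]] - deg[s]; Wp[to] <- Wp[to] + deg[s]
            } else {
              Wa[g[s]] <- Wa[g[s]] - deg[s]; Wa[to] <- Wa[to] + deg[s]
            }
            g[s] <- to
            Q <- Q + dq
          }
        }
      }
      # merge proposal
      mods <- unique(g)
      if (length(mods) >= 2L) {
        ab <- sample(mods, 2L)
        g2 <- g; g2[g2 == ab[2L]] <- ab[1L]
        dq <- q_of(g2) - Q
        if (dq > 0 || stats::runif(1) < exp(dq / T)) {
          g <- g2
          Wp[ab[1L]] <- Wp[ab[1L]] + Wp[ab[2L]]; Wp[ab[2L]] <- 0
          Wa[ab[1L]] <- Wa[ab[1L]] + Wa[ab[2L]]; Wa[ab[2L]] <- 0
          Q <- Q + dq
        }
      }
      # split proposal
      mods <- unique(g)
      big <- mods[vapply(mods, function(m) sum(g == m) >= 2L, logical(1))]
      free <- setdiff(seq_len(S), unique(g))
      if (length(big) > 0L && length(free) > 0L) {
        m <- if (length(big) == 1L) big else sample(big, 1L)
        members <- which(g == m)
        take <- members[stats::runif(length(members)) < 0.5]
        if (length(take) > 0L && length(take) < length(members)) {
          g2 <- g; g2[take] <- free[1L]
          dq <- q_of(g2) - Q
          if (dq > 0 || stats::runif(1) < exp(dq / T)) {
            g <- g2
            Wp[free[1L]] <- sum(deg[is_plant & g == free[1L]])
            Wa[free[1L]] <- sum(deg[!is_plant & g == free[1L]])
            Wp[m] <- sum(deg[is_plant & g == m])
            Wa[m] <- sum(deg[!is_plant & g == m])
            Q <- Q + dq
          }
        }
      }
      if (Q > best_Q + 1e-12) {
        best_Q <- Q; best_g <- g; stall <- 0L
      } else stall <- stall + 1L
      T <- T * cooling
    }
    # greedy refinement of the best state
    g <- best_g
    repeat {
      Wp <- vapply(seq_len(S), function(m) sum(deg[is_plant & g == m]),
                   numeric(1))
      Wa <- vapply(seq_len(S), function(m) sum(deg[!is_plant & g == m]),
                   numeric(1))
      improved <- FALSE
      for (s in seq_len(S)) {
        W_opp <- if (is_plant[s]) Wa else Wp
        cand <- unique(c(unique(g), setdiff(seq_len(S), unique(g))[1L]))
        cand <- cand[!is.na(cand)]
        dqs <- vapply(cand, function(t) delta_single(g, W_opp, s, t),
                      numeric(1))
        b <- which.max(dqs)
        if (dqs[b] > 1e-12) {
          if (is_plant[s]) {
            Wp[g[s]] <- Wp[g[s]] - deg[s]
            Wp[cand[b]] <- Wp[cand[b]] + deg[s]
          } else {
            Wa[g[s]] <- Wa[g[s]] - deg[s]
            Wa[cand[b]] <- Wa[cand[b]] + deg[s]
          }
          g[s] <- cand[b]
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    list(g = g, Q = q_of(g))
  }

  results <- lapply(seq_len(n_restarts), run_restart)
  trace <- vapply(results, `[[`, numeric(1), "Q")
  best <- results[[which.max(trace)]]
  g <- best$g
  if (best$Q < 0) {            # never worse than the one-module partition
    g <- rep(1L, S)
    best$Q <- 0
  }
  g <- as.integer(factor(g, levels = unique(g)))
  names(g) <- c(rownames(A), colnames(A))
  structure(list(name = name, assignment = g, Q = best$Q,
                 n_modules = length(unique(g)), trace = trace,
                 seed = seed),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module partition of '%s': %d modules, Q = %.4f (%d restarts)\n",
              x$name, x$n_modules, x$Q, length(x$trace)))
  invisible(x)
}

#' Species roles from a module partition
#'
#' Within-module standardized degree z (standardized over all species of
#' the same module; 0 where the module sd is 0) and among-module
#' participation c = 1 - sum_m (k_im / k_i)^2. Species are classified into
#' the four role quadrants: peripheral (z < z_thresh, c < c_thresh),
#' connector (z < z_thresh, c >= c_thresh), module hub (z >= z_thresh,
#' c < c_thresh), network hub (both above threshold).
#'
#' @param M a `bipartite_matrix`.
#' @param part a `module_partition` for `M`.
#' @param z_thresh,c_thresh role thresholds (defaults 2.5 and 0.62).
#' @return Data frame: `species`, `side`, `module`, `degree`,
#'   `within_degree`, `z`, `c`, `role`.
#' @export
species_roles <- function(M, part, z_thresh = 2.5, c_thresh = 0.62) {
  stopifnot(inherits(M, "bipartite_matrix"),
            inherits(part, "module_partition"))
  A <- M$cells
  sp <- c(M$plants, M$pollinators)
  g <- part$assignment[sp]
  P <- length(M$plants)
  deg <- c(rowSums(A), colSums(A))
  nbr_mod <- function(i) {
    if (i <= P) g[M$pollinators[A[i, ] == 1]] else g[M$plants[A[, i - P] == 1]]
  }
  within <- vapply(seq_along(sp), function(i) sum(nbr_mod(i) == g[i]),
                   numeric(1))
  cpart <- vapply(seq_along(sp), function(i) {
    km <- table(nbr_mod(i))
    1 - sum((km / deg[i])^2)
  }, numeric(1))
  z <- numeric(length(sp))
  for (m in unique(g)) {
    ix <- which(g == m)
    s <- stats::sd(within[ix])
    z[ix] <- if (is.na(s) || s == 0) 0 else (within[ix] - mean(within[ix])) / s
  }
  role <- ifelse(z >= z_thresh,
                 ifelse(cpart >= c_thresh, "network hub", "module hub"),
                 ifelse(cpart >= c_thresh, "connector", "peripheral"))
  data.frame(species = sp,
             side = rep(c("plants", "pollinators"),
                        c(P, length(M$pollinators))),
             module = as.integer(g), degree = as.integer(deg),
             within_degree = as.integer(within), z = z, c = cpart,
             role = role, stringsAsFactors = FALSE)
}

#' Within- vs between-module placement of added links
#'
#' Labels each link gained by superimposing a new data layer as within
#' (both endpoints in the same module of the base partition) or between,
#' and tests whether the within fraction exceeds chance by a permutation
#' test that shuffles the pollinator endpoints across added links, which
#' preserves every species' added-link count.
#'
#' @param base a `module_partition` of the base network.
#' @param added_links data frame with columns `plant`, `pollinator`; links
#'   absent from the base partition's species set are excluded and counted
#'   separately as `n_new_species_links`.
#' @param n_perm permutations (default 5000).
#' @param seed RNG seed.
#' @return Object of class `link_gain`: list with `n_within`, `n_between`,
#'   `pct_within`, `pct_between`, `per_species` (data frame),
#'   `n_new_species_links`, `p_perm` (NA when no added link is eligible),
#'   `n_perm`, `seed`.
#' @export
link_gain_by_module <- function(base, added_links, n_perm = 5000L,
                                seed = 1L) {
  stopifnot(inherits(base, "module_partition"))
  g <- base$assignment
  known <- added_links$plant %in% names(g) &
    added_links$pollinator %in% names(g)
  new_links <- sum(!known)
  al <- added_links[known, , drop = FALSE]
  if (nrow(al) == 0L) {
    return(structure(list(n_within = 0L, n_between = 0L,
                          pct_within = NA_real_, pct_between = NA_real_,
                          per_species = NULL,
                          n_new_species_links = new_links,
                          p_perm = NA_real_, n_perm = n_perm, seed = seed),
                     class = "link_gain"))
  }
  within <- g[al$plant] == g[al$pollinator]
  per_sp <- function(keys) {
    df <- data.frame(key = keys, within = as.integer(within), total = 1L,
                     stringsAsFactors = FALSE)
    agg <- stats::aggregate(cbind(within, total) ~ key, data = df, FUN = sum)
    agg$pct_within <- 100 * agg$within / agg$total
    agg$pct_between <- 100 - agg$pct_within
    agg
  }
  per_species <- rbind(
    cbind(side = "plants", per_sp(al$plant)),
    cbind(side = "pollinators", per_sp(al$pollinator)))
  obs <- mean(within)
  set.seed(seed)
  gp <- g[al$plant]
  ga <- g[al$pollinator]
  perm <- vapply(seq_len(n_perm), function(i) {
    mean(gp == ga[sample.int(length(ga))])
  }, numeric(1))
  structure(list(
    n_within = sum(within), n_between = sum(!within),
    pct_within = 100 * obs, pct_between = 100 * (1 - obs),
    per_species = per_species, n_new_species_links = new_links,
    p_perm = (1 + sum(perm >= obs)) / (n_perm + 1),
    n_perm = n_perm, seed = seed), class = "link_gain")
}

#' @export
print.link_gain <- function(x, ...) {
  if (is.na(x$pct_within)) {
    cat("link gain: no added links within the base species set\n")
  } else {
    cat(sprintf(
      "link gain: %d within (%.1f%%), %d between (%.1f%%); %d link(s) to new species; permutation p = %.4g\n",
      x$n_within, x$pct_within, x$n_between, x$pct_between,
      x$n_new_species_links, x$p_perm))
  }
  invisible(x)
}
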