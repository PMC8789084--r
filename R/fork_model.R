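#' Specify a replication-fork model for simulation
#'
#' Describes replication of a chromosome in a population of cells: a set of
#' origins that each fire independently with a given efficiency at a fixed
#' time in S phase, bidirectional forks progressing at constant speed, optional
#' stall sites that increase local fork residency, and a uniform background of
#' non-replicative breaks. Time is expressed as a fraction of S phase
#' (0 = entry, 1 = end) and fork speed in bp per unit S-phase time.
#'
#' @param origins data.frame with columns `position` (bp, 0-based),
#'   `efficiency` (probability of firing per cell, in \[0, 1\]) and
#'   `firing_time` (in \[0, 1\]); an optional `chrom` column places origins on
#'   named chromosomes (default: first chromosome of the genome).
#' @param fork_speed bp per unit S-phase time; > 0.
#' @param stall_sites optional data.frame with columns `position`,
#'   `direction` (`"leftward"`, `"rightward"` or `"both"`: which fork
#'   direction is affected) and `residence_weight` (>= 0; a fork inside the
#'   stall zone is observed with probability multiplied by
#'   `1 + residence_weight` relative to an unstalled fork). Optional columns
#'   `chrom` and `width` (spatial extent of the zone in bp, default 500).
#' @param background_break_rate expected non-replicative breaks per bp per
#'   cell, placed uniformly with random strand.
#' @return object of class `fork_model`.
#' @export
fork_model <- function(origins, fork_speed,
                       stall_sites = NULL, background_break_rate = 0) {
  stopifnot(is.data.frame(origins),
            all(c("position", "efficiency", "firing_time") %in% names(origins)))
  if (any(origins$efficiency < 0 | origins$efficiency > 1))
    stop("origin efficiencies must lie in [0, 1]")
  if (any(origins$firing_time < 0 | origins$firing_time > 1))
    stop("firing times must lie in [0, 1]")
  if (!is.numeric(fork_speed) || length(fork_speed) != 1L || fork_speed <= 0)
    stop("fork_speed must be a single value > 0")
  if (!is.null(stall_sites) && nrow(stall_sites)) {
    stopifnot(all(c("position", "direction", "residence_weight") %in%
                  names(stall_sites)))
    if (!all(stall_sites$direction %in% c("leftward", "rightward", "both")))
      stop("stall direction must be leftward, rightward or both")
    w <- stall_sites$residence_weight
    if (any(!is.finite(w)) || any(w < 0))
      stop("residence weights must be finite and >= 0")
    if (is.null(stall_sites$width)) stall_sites$width <- 500
  }
  if (background_break_rate < 0) stop("background_break_rate must be >= 0")
  structure(list(origins = origins, fork_speed = fork_speed,
                 stall_sites = stall_sites,
                 background_break_rate = background_break_rate),
            class = "fork_model")
}

#' @export
print.fork_model <- function(x, ...) {
  cat("fork_model:", nrow(x$origins), "origin(s), speed", x$fork_speed,
      "bp per unit S phase,",
      if (is.null(x$stall_sites)) 0L else nrow(x$stall_sites), "stall site(s),",
      "background", x$background_break_rate, "breaks/bp/cell\n")
  invisible(x)
}

# residence weight experienced by a fork of direction `dir` at position `pos`
stall_weight <- function(stalls, chrom, pos, dir) {
  w <- numeric(length(pos))
  if (is.null(stalls) || !nrow(stalls)) return(w)
  for (i in seq_len(nrow(stalls))) {
    if (!is.null(stalls$chrom) && stalls$chrom[i] != chrom) next
    if (!(stalls$direction[i] %in% c(dir, "both"))) next
    half <- stalls$width[i] / 2
    hit <- pos >= stalls$position[i] - half & pos < stalls$position[i] + half
    w[hit] <- pmax(w[hit], stalls$residence_weight[i])
  }
  w
}

#' Simulate single-cell replication-fork break sites
#'
#' For each cell, every origin fires independently with its efficiency at its
#' firing time; two forks per fired origin progress outward at constant speed;
#' an origin is passively replicated (and does not fire) if a fork from an
#' earlier-firing origin reaches it first; converging forks annihilate at the
#' meeting point implied by firing times and speed, and forks terminate at
#' chromosome ends. The cell is observed at one time drawn uniformly over
#' S phase and each fork still active at that time contributes one break site
#' at its current position: a leftward-moving fork yields a forward-strand
#' site, a rightward-moving fork a reverse-strand site. A fork inside a stall
#' zone is observed with probability multiplied by `1 + residence_weight`
#' (implemented as thinning normalised to the largest residence weight in the
#' model, so relative window densities equal the weight ratio). Background
#' breaks are added uniformly with random strand.
#'
#' @param model a [fork_model()].
#' @param genome `trael_genome` or `DNAStringSet`.
#' @param n_cells number of cells (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @return list of class `trael_sim` with elements `sites` (data.frame: one
#'   molecule per row with `chrom`, `position`, `strand` (`"+"` forward /
#'   `"-"` reverse), `cell`, `origin` (index into `model$origins`, NA for
#'   background) and `source`), plus `model` and `n_cells`.
#' @export
simulate_break_sites <- function(model, genome, n_cells, seed = NULL) {
  stopifnot(inherits(model, "fork_model"), n_cells >= 1)
  if (!is.null(seed)) set.seed(seed)
  lens <- genome_lengths(genome)
  org <- model$origins
  if (is.null(org$chrom)) org$chrom <- names(lens)[1L]
  if (all(org$efficiency == 0) && model$background_break_rate == 0)
    stop("no signal to emit: all origin efficiencies zero and no background breaks")
  if (any(org$position < 0 | org$position >= lens[org$chrom]))
    stop("origin position outside chromosome")
  stalls <- model$stall_sites
  if (!is.null(stalls) && is.null(stalls$chrom) && nrow(stalls))
    stalls$chrom <- names(lens)[1L]
  wmax <- if (is.null(stalls) || !nrow(stalls)) 0 else max(stalls$residence_weight)
  v <- model$fork_speed

  out <- vector("list", length(lens) + 1L)
  for (ci in seq_along(lens)) {
    ch <- names(lens)[ci]
    L <- lens[[ci]]
    oc <- org[org$chrom == ch, , drop = FALSE]
    if (!nrow(oc)) next
    oc <- oc[order(oc$position), , drop = FALSE]
    O <- nrow(oc)
    x <- oc$position; t0 <- oc$firing_time; eff <- oc$efficiency
    oidx <- as.integer(rownames(oc))
    if (anyNA(oidx)) oidx <- match(paste(oc$position, oc$firing_time),
                                   paste(org$position, org$firing_time))

    fired <- matrix(runif(n_cells * O), n_cells, O) <=
      matrix(eff, n_cells, O, byrow = TRUE)
    # passive replication: an origin cannot fire if already replicated by an
    # earlier-firing origin's fork at its firing time
    active <- fired
    t_ord <- order(t0)
    if (O > 1L) {
      for (k in 2:O) {
        o <- t_ord[k]
        for (j in t_ord[seq_len(k - 1L)]) {
          if (t0[j] + abs(x[o] - x[j]) / v < t0[o]) {
            active[, o] <- active[, o] & !active[, j]
          }
        }
      }
    }
    Tobs <- runif(n_cells)

    # annihilation between adjacent fired origins
    left_dead <- matrix(FALSE, n_cells, O)
    right_dead <- matrix(FALSE, n_cells, O)
    prev <- integer(n_cells)
    for (o in seq_len(O)) {
      a <- active[, o]
      hp <- which(a & prev > 0L)
      if (length(hp)) {
        p <- prev[hp]
        tmeet <- (x[o] - x[p]) / (2 * v) + (t0[p] + t0[o]) / 2
        dead <- Tobs[hp] >= tmeet
        left_dead[hp, o] <- dead
        right_dead[cbind(hp, p)] <- dead
      }
      prev[a] <- o
    }

    res <- vector("list", 2L * O)
    for (o in seq_len(O)) {
      cells <- which(active[, o] & Tobs >= t0[o])
      if (!length(cells)) next
      dt <- Tobs[cells] - t0[o]
      lp <- x[o] - v * dt
      okL <- !left_dead[cells, o] & lp >= 0
      rp <- x[o] + v * dt
      okR <- !right_dead[cells, o] & rp <= L - 1
      res[[2L * o - 1L]] <- data.frame(
        position = round(lp[okL]), strand = "+", cell = cells[okL],
        origin = oidx[o], dir = "leftward")
      res[[2L * o]] <- data.frame(
        position = round(rp[okR]), strand = "-", cell = cells[okR],
        origin = oidx[o], dir = "rightward")
    }
    sites <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
    if (!is.null(sites) && nrow(sites)) {
      w <- ifelse(sites$strand == "+",
                  stall_weight(stalls, ch, sites$position, "leftward"),
                  stall_weight(stalls, ch, sites$position, "rightward"))
      keep <- runif(nrow(sites)) < (1 + w) / (1 + wmax)
      sites <- sites[keep, , drop = FALSE]
      sites$chrom <- ch
      sites$source <- "fork"
      out[[ci]] <- sites[, c("chrom", "position", "strand", "cell",
                             "origin", "source")]
    }
  }

  if (model$background_break_rate > 0) {
    bg <- vector("list", length(lens))
    for (ci in seq_along(lens)) {
      L <- lens[[ci]]
      nb <- rpois(1L, model$background_break_rate * L * n_cells)
      if (nb > 0L) {
        bg[[ci]] <- data.frame(
          chrom = names(lens)[ci],
          position = sample.int(L, nb, replace = TRUE) - 1L,
          strand = sample(c("+", "-"), nb, replace = TRUE),
          cell = sample.int(n_cells, nb, replace = TRUE),
          origin = NA_integer_, source = "background")
      }
    }
    out[[length(lens) + 1L]] <- do.call(rbind, bg[!vapply(bg, is.null, TRUE)])
  }

  sites <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(sites)) {
    sites <- data.frame(chrom = character(), position = numeric(),
                        strand = character(), cell = integer(),
                        origin = integer(), source = character())
  }
  rownames(sites) <- NULL
  structure(list(sites = sites, model = model, n_cells = n_cells),
            class = "trael_sim")
}

#' @export
print.trael_sim <- function(x, ...) {
  cat("trael_sim:", nrow(x$sites), "break-site molecules from",
      x$n_cells, "cells\n")
  invisible(x)
}

#' Draw a random multi-origin fork model
#'
#' Convenience generator for benchmarking origin recovery: 3-6 efficient
#' origins (efficiency 0.7-1) spaced at least 40 kb apart on one chromosome,
#' firing at 0.1-0.4 of S phase with a fork speed fast enough that every
#' adjacent fork pair converges within S phase (so passive replication never
#' silences an origin and every inter-origin gap carries a convergence zone).
#'
#' @param seed integer seed.
#' @param n_origins number of origins (default: drawn from 3:6).
#' @param spacing mean origin spacing in bp.
#' @param fork_speed bp per unit S-phase time.
#' @return list with `model` (a [fork_model()]), `spec` (a [genome_spec()]
#'   for the matching chromosome) and `origins` (the true origin table).
#' @export
random_fork_model <- function(seed, n_origins = NULL, spacing = 60000,
                              fork_speed = 1e5) {
  set.seed(seed)
  k <- if (is.null(n_origins)) sample(3:6, 1L) else n_origins
  L <- as.integer(spacing * k + 40000)
  pos <- 50000 + (seq_len(k) - 1L) * spacing +
    round(runif(k, -spacing / 6, spacing / 6))
  org <- data.frame(position = pos,
                    efficiency = runif(k, 0.7, 1),
                    firing_time = runif(k, 0.1, 0.4))
  list(model = fork_model(org, fork_speed = fork_speed),
       spec = genome_spec(setNames(L, "chr1"), seed = seed + 1L),
       origins = org)
}
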