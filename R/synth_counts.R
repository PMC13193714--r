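#' Configuration for a simulated gene x cell count matrix
#'
#' Markers get configurable per-cell positivity probabilities
#' (`P(count >= 1)`) and, optionally, pairwise co-positivity
#' probabilities. Pairs may share a marker (e.g. one probe gene jointly
#' specified with both receptor markers) as long as the pair graph is
#' acyclic; the joint structure is then realized by conditional sampling
#' along the tree. Remaining (background) genes are detected independently
#' at `background_detect` per cell. Positive entries get counts
#' `1 + Poisson(count_lambda)` so the single-copy positivity rule is
#' exactly the configured Bernoulli.
#'
#' @param n_genes Total genes including markers.
#' @param n_cells Number of cells.
#' @param marker_names Character vector of marker gene names.
#' @param positivity_probs Named per-marker `P(count >= 1)`.
#' @param joint_probs `NULL`, or data frame `marker_a`, `marker_b`,
#'   `p_joint` with `P(both >= 1)`; must satisfy
#'   `max(0, pa + pb - 1) <= p_joint <= min(pa, pb)`.
#' @param background_detect Detection probability of non-marker genes.
#' @param count_lambda Poisson mean of extra copies in positive cells.
#' @param seed Integer RNG seed.
#' @return A validated `count_sim_config` list.
#' @export
count_sim_config <- function(n_genes, n_cells, marker_names,
                             positivity_probs, joint_probs = NULL,
                             background_detect = 0.3, count_lambda = 1,
                             seed = 1L) {
  check_number(n_genes, "n_genes", lower = 1)
  check_number(n_cells, "n_cells", lower = 1)
  if (length(marker_names) > n_genes) {
    stop_field("marker_names", "more markers than genes")
  }
  if (anyDuplicated(marker_names)) {
    stop_field("marker_names", "duplicate marker names")
  }
  if (is.null(names(positivity_probs))) names(positivity_probs) <- marker_names
  if (!setequal(names(positivity_probs), marker_names)) {
    stop_field("positivity_probs", "must be named by marker_names")
  }
  if (any(positivity_probs < 0 | positivity_probs > 1)) {
    stop_field("positivity_probs", "probabilities must lie in [0, 1]")
  }
  if (!is.null(joint_probs)) {
    stopifnot(is.data.frame(joint_probs),
              all(c("marker_a", "marker_b", "p_joint") %in% names(joint_probs)))
    for (i in seq_len(nrow(joint_probs))) {
      a <- joint_probs$marker_a[i]; b <- joint_probs$marker_b[i]
      pj <- joint_probs$p_joint[i]
      if (!a %in% marker_names || !b %in% marker_names || a == b) {
        stop_field("joint_probs", sprintf("bad pair (%s, %s)", a, b))
      }
      pa <- positivity_probs[[a]]; pb <- positivity_probs[[b]]
      if (pj > min(pa, pb) + 1e-12 || pj < max(0, pa + pb - 1) - 1e-12) {
        stop_field("joint_probs",
                   sprintf("p_joint=%.3g infeasible for marginals %.3g/%.3g",
                           pj, pa, pb))
      }
    }
    # acyclicity of the pair graph (forest): edges <= nodes - components
    edges <- unique(joint_probs[c("marker_a", "marker_b")])
    if (has_cycle(edges, marker_names)) {
      stop_field("joint_probs", "pair graph must be acyclic (a forest)")
    }
  }
  check_number(background_detect, "background_detect", lower = 0, upper = 1)
  check_number(count_lambda, "count_lambda", lower = 0)
  structure(list(n_genes = as.integer(n_genes),
                 n_cells = as.integer(n_cells),
                 marker_names = marker_names,
                 positivity_probs = positivity_probs,
                 joint_probs = joint_probs,
                 background_detect = background_detect,
                 count_lambda = count_lambda,
                 seed = as.integer(seed)),
            class = "count_sim_config")
}

has_cycle <- function(edges, nodes) {
  # union-find over marker indices
  p <- seq_along(nodes); names(p) <- nodes
  root <- function(i) { while (p[i] != i) i <- p[i]; i }
  for (k in seq_len(nrow(edges))) {
    i <- root(match(edges$marker_a[k], nodes))
    j <- root(match(edges$marker_b[k], nodes))
    if (i == j) return(TRUE)
    p[i] <- j
  }
  FALSE
}

#' Simulate a sparse gene x cell count matrix
#'
#' @param cfg A [count_sim_config()].
#' @return List: `counts` (a `Matrix::dgCMatrix`, genes x cells, with
#'   gene/cell dimnames), `positive` (logical marker x cell matrix of the
#'   latent positivity draws, the ground truth).
#' @export
simulate_count_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "count_sim_config"))
  nm <- length(cfg$marker_names)
  genes <- c(cfg$marker_names,
             sprintf("gene%04d", seq_len(cfg$n_genes - nm)))
  cells <- sprintf("cell%06d", seq_len(cfg$n_cells))

  withr::with_seed(cfg$seed, {
    pos <- matrix(FALSE, nm, cfg$n_cells,
                  dimnames = list(cfg$marker_names, NULL))
    # Roots/isolated markers are drawn marginally; each remaining marker
    # is drawn conditional on its already-sampled tree neighbor so every
    # configured pairwise joint holds exactly. BFS over the (acyclic)
    # pair graph fixes a valid sampling order.
    edges <- cfg$joint_probs
    done <- logical(nm); names(done) <- cfg$marker_names
    order_plan <- list()  # each: list(marker, parent = NULL|name, edge_row)
    for (mk in cfg$marker_names) {
      if (done[mk]) next
      queue <- mk
      order_plan[[length(order_plan) + 1L]] <- list(marker = mk, parent = NULL)
      done[mk] <- TRUE
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        if (!is.null(edges)) {
          hit <- which(edges$marker_a == cur | edges$marker_b == cur)
          for (h in hit) {
            nb <- if (edges$marker_a[h] == cur) edges$marker_b[h] else edges$marker_a[h]
            if (!done[nb]) {
              order_plan[[length(order_plan) + 1L]] <-
                list(marker = nb, parent = cur, edge_row = h)
              done[nb] <- TRUE
              queue <- c(queue, nb)
            }
          }
        }
      }
    }
    for (step in order_plan) {
      mk <- step$marker
      p_mk <- cfg$positivity_probs[[mk]]
      if (is.null(step$parent)) {
        pos[mk, ] <- stats::runif(cfg$n_cells) < p_mk
      } else {
        other <- step$parent
        pj <- edges$p_joint[step$edge_row]
        p_other <- cfg$positivity_probs[[other]]
        p_given_pos <- if (p_other > 0) pj / p_other else 0
        p_given_neg <- if (p_other < 1) (p_mk - pj) / (1 - p_other) else 0
        u <- stats::runif(cfg$n_cells)
        pos[mk, ] <- ifelse(pos[other, ], u < p_given_pos, u < p_given_neg)
      }
    }

    # marker counts: positives get 1 + Poisson extras
    trip_i <- integer(); trip_j <- integer(); trip_x <- integer()
    for (k in seq_len(nm)) {
      j <- which(pos[k, ])
      if (length(j)) {
        trip_i <- c(trip_i, rep(k, length(j)))
        trip_j <- c(trip_j, j)
        trip_x <- c(trip_x, 1L + stats::rpois(length(j), cfg$count_lambda))
      }
    }
    # background genes: independent detection
    for (k in seq_len(cfg$n_genes - nm)) {
      j <- which(stats::runif(cfg$n_cells) < cfg$background_detect)
      if (length(j)) {
        trip_i <- c(trip_i, rep(nm + k, length(j)))
        trip_j <- c(trip_j, j)
        trip_x <- c(trip_x, 1L + stats::rpois(length(j), cfg$count_lambda))
      }
    }
    counts <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                                   dims = c(cfg$n_genes, cfg$n_cells),
                                   dimnames = list(genes, cells))
    list(counts = counts, positive = pos)
  })
}
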