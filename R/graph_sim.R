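#' Construct a connectome graph
#'
#' An undirected simple graph over brain regions: no self-loops, each
#' unordered pair stored once. `pedge` is the realized edge density
#' 2|E| / (n(n-1)); removing an edge removes both directions at once, as
#' the undirected representation implies.
#'
#' @param n_nodes Number of regions.
#' @param edges Two-column integer matrix of node pairs (1-based), one row
#'   per undirected edge.
#' @return Object of class `connectome`.
#' @export
connectome <- function(n_nodes, edges) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(n_nodes >= 1L)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L | edges > n_nodes)) stop("edge endpoints out of range")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    # canonical order, one row per unordered pair
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (anyDuplicated(edges)) stop("duplicate edges")
  }
  structure(
    list(
      n_nodes = n_nodes,
      edges = edges,
      pedge = if (n_nodes > 1L) 2 * nrow(edges) / (n_nodes * (n_nodes - 1)) else 0
    ),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome>", x$n_nodes, "nodes,", nrow(x$edges),
      "edges (density", signif(x$pedge, 4), ")\n")
  invisible(x)
}

#' Average degree of a connectome
#' @param g A [connectome()].
#' @return 2|E| / n_nodes.
#' @export
avg_degree <- function(g) {
  stopifnot(inherits(g, "connectome"))
  2 * nrow(g$edges) / g$n_nodes
}

#' Erdős–Rényi surrogate connectome
#'
#' Random stand-in for a diffusion-MRI structure: each unordered node pair
#' carries an edge independently with probability `pedge`.
#'
#' @param n_nodes Number of regions.
#' @param pedge Edge probability in \[0, 1\].
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A [connectome()].
#' @export
er_connectome <- function(n_nodes, pedge, seed = NULL) {
  stopifnot(pedge >= 0, pedge <= 1)
  gen <- function() {
    g <- igraph::sample_gnp(n_nodes, pedge, directed = FALSE, loops = FALSE)
    connectome(n_nodes, igraph::as_edgelist(g, names = FALSE))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Configuration of a graph-Ising simulation
#'
#' Defaults follow the degradation protocol: base coupling `lam0 = 86`
#' (so the effective mean-field coupling is `lam0 * pedge`), 2500 recorded
#' steps of 640 single-spin-flip attempts (10 flips attempted 64 times),
#' and 5 undirected edges removed per round for 83 rounds. No burn-in is
#' discarded by default; when measuring equilibrium moments on their own,
#' >= 100 burn-in steps are recommended.
#'
#' @param seed Integer seed; mandatory, every run must be reproducible.
#' @param lam0 Base coupling lambda_0; the per-edge log-weight is
#'   `2 * lam0 / n_nodes^2` (see [metropolis_run()]).
#' @param n_steps Recorded time steps.
#' @param flips_per_step Single-spin-flip attempts per recorded step.
#' @param removal_batch Undirected edges removed per round.
#' @param removal_rounds Number of removal rounds.
#' @param burn_in Steps discarded before recording (default 0).
#' @param s_star Synchrony threshold; `NULL` means calibrate for the
#'   graph's node count at run time.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed, lam0 = 86, n_steps = 2500L, flips_per_step = 640L,
                       removal_batch = 5L, removal_rounds = 83L,
                       burn_in = 0L, s_star = NULL) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("a single integer seed is mandatory")
  }
  stopifnot(n_steps >= 1L, flips_per_step >= 1L, removal_batch >= 1L,
            removal_rounds >= 0L, burn_in >= 0L)
  structure(
    list(seed = as.integer(seed), lam0 = lam0, n_steps = as.integer(n_steps),
         flips_per_step = as.integer(flips_per_step),
         removal_batch = as.integer(removal_batch),
         removal_rounds = as.integer(removal_rounds),
         burn_in = as.integer(burn_in), s_star = s_star),
    class = "sim_config"
  )
}

#' Effective mean-field coupling of a simulated graph
#'
#' With per-edge log-weight `2 * lam0 / n^2`, the graph-averaged coupling
#' matches the mean-field model at `lam0 * pedge`; this is the scale on
#' which simulated and fitted couplings are compared.
#'
#' @param g A [connectome()].
#' @param cfg A [sim_config()] (or a number taken as lam0).
#' @return `lam0 * pedge`.
#' @export
effective_lambda <- function(g, cfg) {
  lam0 <- if (inherits(cfg, "sim_config")) cfg$lam0 else cfg
  lam0 * g$pedge
}

edges_to_csr <- function(n_nodes, edges) {
  deg <- integer(n_nodes)
  if (nrow(edges) > 0L) {
    tb <- tabulate(c(edges[, 1], edges[, 2]), nbins = n_nodes)
    deg <- tb
  }
  ptr <- c(0L, cumsum(deg))
  idx <- integer(sum(deg))
  if (nrow(edges) > 0L) {
    ord <- order(c(edges[, 1], edges[, 2]))
    nb <- c(edges[, 2], edges[, 1])[ord]
    idx <- nb - 1L
  }
  list(ptr = as.integer(ptr), idx = as.integer(idx))
}

#' Metropolis-Hastings Ising dynamics on a connectome
#'
#' Spins start uniformly at random; each recorded step attempts
#' `flips_per_step` single-spin flips at uniformly random nodes, accepted
#' with probability min(1, exp(dlogW)) where
#' logW = J_edge * sum over edges of s_i s_j. The per-edge coupling is
#' `J_edge = 2 * lam0 / n_nodes^2`: since the mean-field weight
#' exp(lambda n^2 / N^2) counts each unordered pair twice through n^2, this
#' makes the effective coupling of the graph equal `lam0 * pedge`, and on a
#' complete graph the stationary synchrony distribution is exactly
#' [synchrony_pmf()] at that coupling. Synchrony is recorded once per step,
#' after its attempts.
#'
#' @param g A [connectome()]; an empty graph means free spins.
#' @param cfg A [sim_config()].
#' @return A `synchrony` vector of length `cfg$n_steps`.
#' @export
metropolis_run <- function(g, cfg) {
  stopifnot(inherits(g, "connectome"), inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, metropolis_run_impl(g, cfg))
}

# runs under the caller's RNG state (edge_removal_experiment seeds once)
metropolis_run_impl <- function(g, cfg) {
  csr <- edges_to_csr(g$n_nodes, g$edges)
  j_edge <- 2 * cfg$lam0 / g$n_nodes^2
  init <- sample(c(-1L, 1L), g$n_nodes, replace = TRUE)
  s <- metropolis_core(csr$ptr, csr$idx, j_edge, init,
                       cfg$n_steps, cfg$flips_per_step, cfg$burn_in)
  structure(s, n_regions = g$n_nodes, class = "synchrony")
}

#' Random edge-removal degradation experiment
#'
#' Simulates progressive loss of anatomical connections: run the Ising
#' dynamics on the current graph, record its Pseg, then delete
#' `removal_batch` undirected edges uniformly at random (both directions of
#' each edge vanish together), and repeat for `removal_rounds` rounds.
#' Reports the Spearman correlation between average degree and Pseg over
#' all recorded rounds.
#'
#' @param g Starting [connectome()].
#' @param cfg A [sim_config()]; `cfg$s_star = NULL` calibrates the
#'   threshold for `g$n_nodes` regions (the simulation's effective region
#'   count equals its node count).
#' @return Object of class `removal_trajectory`: list with `records`
#'   (tibble of `round`, `n_edges`, `avg_degree`, `pseg`), `spearman_rho`,
#'   `p_value`, `s_star`, `config`.
#' @export
edge_removal_experiment <- function(g, cfg) {
  stopifnot(inherits(g, "connectome"), inherits(cfg, "sim_config"))
  s_star <- if (is.null(cfg$s_star)) calibrate_s_star(g$n_nodes) else cfg$s_star
  planned <- cfg$removal_batch * cfg$removal_rounds
  if (nrow(g$edges) < planned) {
    warning("graph has ", nrow(g$edges), " edges but the protocol removes ",
            planned, "; trajectory will be truncated")
  }
  records <- withr::with_seed(cfg$seed, {
    cur <- g
    out <- vector("list", cfg$removal_rounds + 1L)
    for (r in 0:cfg$removal_rounds) {
      s <- metropolis_run_impl(cur, cfg)
      out[[r + 1L]] <- tibble::tibble(
        round = r,
        n_edges = nrow(cur$edges),
        avg_degree = avg_degree(cur),
        pseg = pseg_empirical(s, s_star)$pseg
      )
      if (r == cfg$removal_rounds) break
      if (nrow(cur$edges) < cfg$removal_batch) {
        warning("edges exhausted after round ", r, "; truncating")
        out <- out[seq_len(r + 1L)]
        break
      }
      keep <- sort(sample.int(nrow(cur$edges),
                              nrow(cur$edges) - cfg$removal_batch))
      cur <- connectome(cur$n_nodes, cur$edges[keep, , drop = FALSE])
    }
    dplyr::bind_rows(out)
  })
  rho <- NA_real_
  p <- NA_real_
  if (nrow(records) >= 3L && stats::sd(records$avg_degree) > 0) {
    ct <- suppressWarnings(
      stats::cor.test(records$avg_degree, records$pseg, method = "spearman",
                      exact = FALSE)
    )
    rho <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(
    list(records = records, spearman_rho = rho, p_value = p,
         s_star = s_star, config = cfg),
    class = "removal_trajectory"
  )
}

#' @export
print.removal_trajectory <- function(x, ...) {
  cat("<removal_trajectory>", nrow(x$records), "rounds; Spearman rho(avg degree, Pseg) =",
      signif(x$spearman_rho, 4), "\n")
  print(x$records, n = 6)
  invisible(x)
}

#' @rdname edge_removal_experiment
#' @param x A `removal_trajectory`.
#' @param ... Unused.
#' @method tidy removal_trajectory
#' @export
tidy.removal_trajectory <- function(x, ...) x$records

#' @rdname edge_removal_experiment
#' @method glance removal_trajectory
#' @export
glance.removal_trajectory <- function(x, ...) {
  tibble::tibble(
    spearman_rho = x$spearman_rho,
    p_value = x$p_value,
    n_rounds = nrow(x$records),
    s_star = x$s_star,
    lam0 = x$config$lam0
  )
}
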