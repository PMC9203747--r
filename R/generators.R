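#' Generate a random Boolean network
#'
#' Wiring: for \code{k = 1} a directed ring (node \eqn{i} regulated by node
#' \eqn{i - 1}); for \code{k = 2} an undirected ring (both ring neighbours);
#' for \code{k >= 3}, \code{k} distinct regulators sampled uniformly per
#' node, resampled until no node is isolated (every node regulates at least
#' one node). Each truth-table output bit is 1 with probability \code{bias}
#' independently (0.5 = unbiased).
#'
#' @param n number of nodes (\eqn{\ge 1}; \eqn{\ge 3} for ring wirings).
#' @param k homogeneous in-degree (\eqn{1 \le k}; \eqn{k < n} for random
#'   wiring).
#' @param bias probability that an output bit equals 1.
#' @param seed optional RNG seed; generation is bit-reproducible given the
#'   seed.
#' @return a \code{\link{boolean_network}} with nodes named \code{n1..nN}.
#' @export
make_rbn <- function(n, k, bias = 0.5, seed = NULL) {
  n <- as.integer(n)
  k <- as.integer(k)
  if (n < 1L || k < 1L) stop("`n` and `k` must be positive", call. = FALSE)
  if (bias < 0 || bias > 1) stop("`bias` must be in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (k == 1L) {
    regs <- lapply(seq_len(n), function(i) ((i - 2L) %% n) + 1L)
  } else if (k == 2L) {
    if (n < 3L) stop("ring wiring for k = 2 needs n >= 3", call. = FALSE)
    regs <- lapply(seq_len(n), function(i)
      c(((i - 2L) %% n) + 1L, (i %% n) + 1L))
  } else {
    if (k >= n)
      stop("random wiring requires k < n", call. = FALSE)
    tries <- 0L
    repeat {
      regs <- lapply(seq_len(n), function(i) sample.int(n, k))
      if (all(seq_len(n) %in% unlist(regs))) break
      tries <- tries + 1L
      if (tries > 1000L)
        stop("could not wire a network without isolated nodes", call. = FALSE)
    }
  }
  funs <- lapply(seq_len(n), function(i)
    as.integer(stats::runif(2^k) < bias))
  boolean_network(paste0("n", seq_len(n)), regs, funs)
}

# ---- bundled gene-regulatory-network models -------------------------------

#' Load a bundled gene regulatory network model
#'
#' Returns a transcription of a published Boolean GRN model shipped with the
#' package (see the provenance headers of the files under
#' \code{inst/extdata}):
#' \describe{
#'   \item{\code{spn17}}{single-cell Drosophila melanogaster segment
#'     polarity network, N = 17, of which SLP, nWG and nHH are external
#'     inputs with no regulators (frozen); 10 attractors under synchronous
#'     update.}
#'   \item{\code{yeast12}}{budding yeast cell-cycle threshold network,
#'     N = 12 (11 regulatory nodes plus the frozen cell-size signal); 11
#'     attractors under synchronous update.}
#'   \item{\code{parasegment60}}{four-cell Drosophila parasegment: four
#'     copies of the 15 intracellular segment-polarity nodes coupled through
#'     neighbouring-cell WG/hh/HH signals on a periodic ring, one frozen SLP
#'     input per cell.}
#' }
#' The T-LGL leukemia and ER+ breast-cancer models referenced in the
#' literature are not bundled: their full rule sets could not be transcribed
#' and verified offline.
#'
#' @param name one of \code{"spn17"}, \code{"yeast12"},
#'   \code{"parasegment60"}.
#' @return a \code{\link{boolean_network}}.
#' @export
load_fixture <- function(name) {
  files <- c(spn17 = "spn17.bnet", yeast12 = "yeast12.json",
             parasegment60 = "parasegment60.json")
  if (!name %in% names(files))
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(names(files), collapse = ", ")), call. = FALSE)
  path <- system.file("extdata", files[[name]], package = "boolcontrol",
                      mustWork = TRUE)
  read_boolean_network(path)
}

# Threshold-rule network builder (used to construct the yeast cell-cycle
# model): sigma_i(t+1) = 1 if sum_j w_ij sigma_j(t) > 0, 0 if < 0; on a tie,
# self-degrading nodes decay to 0, all others retain their state (and thus
# gain a self-input).
threshold_network <- function(nodes, weights, self_degrading) {
  n <- length(nodes)
  regs <- vector("list", n)
  funs <- vector("list", n)
  for (i in seq_len(n)) {
    w <- weights[, i]
    r <- which(w != 0)
    retain <- !self_degrading[i]
    r_all <- if (retain) sort(unique(c(r, i))) else r
    if (!length(r_all)) {          # pure input node: frozen
      regs[[i]] <- integer(0)
      funs[[i]] <- c(0L, 1L)
      next
    }
    k <- length(r_all)
    out <- integer(2^k)
    for (row in 0:(2^k - 1L)) {
      bits <- row_to_bits(row, k)
      st <- integer(n)
      st[r_all] <- bits
      total <- sum(w[r] * st[r])
      out[row + 1L] <- if (total > 0) 1L else if (total < 0) 0L else
        if (retain) st[i] else 0L
    }
    regs[[i]] <- r_all
    funs[[i]] <- out
  }
  boolean_network(nodes, regs, funs)
}

# Budding yeast cell-cycle network (11 threshold nodes + frozen cell-size
# signal). Activating edges +1, inhibiting edges -1; the five nodes with
# self-degradation loops decay on a tie, the others retain their state.
build_yeast_cellcycle <- function() {
  nodes <- c("CellSize", "Cln3", "MBF", "SBF", "Cln12", "Cdh1", "Swi5",
             "Cdc2014", "Clb56", "Sic1", "Clb12", "Mcm1")
  n <- length(nodes)
  w <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  act <- list(
    c("CellSize", "Cln3"),
    c("Cln3", "MBF"), c("Cln3", "SBF"),
    c("SBF", "Cln12"),
    c("MBF", "Clb56"),
    c("Cdc2014", "Swi5"), c("Cdc2014", "Cdh1"), c("Cdc2014", "Sic1"),
    c("Clb56", "Mcm1"), c("Clb56", "Clb12"),
    c("Clb12", "Mcm1"), c("Clb12", "Cdc2014"),
    c("Mcm1", "Clb12"), c("Mcm1", "Cdc2014"), c("Mcm1", "Swi5"),
    c("Swi5", "Sic1"))
  inh <- list(
    c("Cln12", "Sic1"), c("Cln12", "Cdh1"),
    c("Clb56", "Sic1"), c("Clb56", "Cdh1"),
    c("Clb12", "Sic1"), c("Clb12", "Cdh1"), c("Clb12", "SBF"),
    c("Clb12", "MBF"), c("Clb12", "Swi5"),
    c("Sic1", "Clb56"), c("Sic1", "Clb12"),
    c("Cdh1", "Clb12"),
    c("Cdc2014", "Clb56"), c("Cdc2014", "Clb12"))
  for (e in act) w[e[1L], e[2L]] <- 1L
  for (e in inh) w[e[1L], e[2L]] <- -1L
  self_deg <- nodes %in% c("Cln3", "Cln12", "Swi5", "Cdc2014", "Mcm1")
  threshold_network(nodes, w, self_deg)
}

#' Named phenotype attractors of the parasegment network
#'
#' Enumerates the fixed points of the four-cell parasegment model under the
#' wild-type SLP prepattern (SLP off in cells 1-2, on in cells 3-4) via
#' \code{\link{fixed_points}} and returns the six biologically named
#' patterns, identified by their wg/en expression signature: wild type
#' (wg in cell 4, en in cell 1), wild type variant (same, with PTC on in
#' cell 1), ectopic (wg in cell 3, en in cell 2), ectopic variant (same,
#' with PTC on in cell 2), broad stripes (wg in cells 3-4, en in cells
#' 1-2), and no segmentation (neither wg nor en expressed).
#'
#' @param net the \code{parasegment60} network from
#'   \code{\link{load_fixture}}.
#' @return named list of six single-row 0/1 matrices (fixed points).
#' @export
parasegment_attractors <- function(net) {
  stopifnot(identical(n_nodes(net), 60L))
  slp <- paste0("SLP_", 1:4)
  fp <- fixed_points(net, seed_set(net, c(0L, 0L, 1L, 1L), nodes = slp))
  wg <- fp[, paste0("wg_", 1:4), drop = FALSE]
  en <- fp[, paste0("en_", 1:4), drop = FALSE]
  ptc <- fp[, paste0("PTC_", 1:4), drop = FALSE]
  sig <- function(wg_on, en_on) {
    apply(wg, 1L, function(r) all(r == as.integer(1:4 %in% wg_on))) &
      apply(en, 1L, function(r) all(r == as.integer(1:4 %in% en_on)))
  }
  pick <- function(cond) {
    i <- which(cond)
    if (length(i) != 1L)
      stop("phenotype signature did not identify a unique fixed point",
           call. = FALSE)
    fp[i, , drop = FALSE]
  }
  list(
    wildtype = pick(sig(4L, 1L) & ptc[, 1L] == 0L),
    wildtype_variant = pick(sig(4L, 1L) & ptc[, 1L] == 1L),
    ectopic = pick(sig(3L, 2L) & ptc[, 2L] == 0L),
    ectopic_variant = pick(sig(3L, 2L) & ptc[, 2L] == 1L),
    broad_stripes = pick(sig(3:4, 1:2)),
    no_segmentation = pick(sig(integer(0), integer(0))))
}

# Four-cell Drosophila parasegment: per-cell segment-polarity rules with
# intercellular WG/hh/HH signalling on a periodic ring of cells; SLP is a
# frozen external input in every cell.
build_parasegment <- function(cells = 4L) {
  per <- c("SLP", "wg", "WG", "en", "EN", "hh", "HH", "ptc", "PTC", "PH",
           "SMO", "ci", "CI", "CIA", "CIR")
  nodes <- as.vector(outer(per, seq_len(cells),
                           function(g, c) paste0(g, "_", c)))
  id <- function(g, c) paste0(g, "_", ((c - 1L) %% cells) + 1L)
  rules <- character(0)
  for (c in seq_len(cells)) {
    nb <- c(c - 1L, c + 1L)
    nWG <- paste0("(", id("WG", nb[1L]), " | ", id("WG", nb[2L]), ")")
    nhh <- paste0("(", id("hh", nb[1L]), " | ", id("hh", nb[2L]), ")")
    nHH <- paste0("(", id("HH", nb[1L]), " | ", id("HH", nb[2L]), ")")
    r <- c(
      sprintf("%s, %s", id("SLP", c), id("SLP", c)),
      sprintf("%s, (%s & %s & !%s) | (%s & (%s | %s) & !%s)",
              id("wg", c), id("CIA", c), id("SLP", c), id("CIR", c),
              id("wg", c), id("CIA", c), id("SLP", c), id("CIR", c)),
      sprintf("%s, %s", id("WG", c), id("wg", c)),
      sprintf("%s, %s & !%s", id("en", c), nWG, id("SLP", c)),
      sprintf("%s, %s", id("EN", c), id("en", c)),
      sprintf("%s, %s & !%s", id("hh", c), id("EN", c), id("CIR", c)),
      sprintf("%s, %s", id("HH", c), id("hh", c)),
      sprintf("%s, %s & !%s & !%s", id("ptc", c), id("CIA", c),
              id("EN", c), id("CIR", c)),
      sprintf("%s, %s | (%s & !%s)", id("PTC", c), id("ptc", c),
              id("PTC", c), nHH),
      sprintf("%s, %s & %s", id("PH", c), id("PTC", c), nHH),
      sprintf("%s, !%s | %s", id("SMO", c), id("PTC", c), nHH),
      sprintf("%s, !%s", id("ci", c), id("EN", c)),
      sprintf("%s, %s", id("CI", c), id("ci", c)),
      sprintf("%s, %s & (%s | %s)", id("CIA", c), id("CI", c),
              id("SMO", c), nhh),
      sprintf("%s, %s & !%s & !%s", id("CIR", c), id("CI", c),
              id("SMO", c), nhh))
    rules <- c(rules, r)
  }
  # keep declaration order cell-major as in `nodes`
  ord <- match(sub(",.*$", "", rules), nodes)
  parse_bnet_lines(c("targets, factors", rules[order(ord)]))
}
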