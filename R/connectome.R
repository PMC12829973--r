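`%||%` <- function(a, b) if (is.null(a)) b else a

# Bernoulli edge sampling between id sets; chunked over targets to bound the
# size of the uniform draw. Returns global 1-based ids.
.bernoulli_edges <- function(src_ids, tgt_ids, p, no_self = FALSE) {
  ns <- length(src_ids); nt <- length(tgt_ids)
  if (is.na(p) || p <= 0 || ns == 0L || nt == 0L)
    return(list(src = integer(0), tgt = integer(0)))
  chunk <- max(1L, as.integer(2e6 / ns))
  acc_s <- vector("list", ceiling(nt / chunk))
  acc_t <- vector("list", ceiling(nt / chunk))
  ci <- 0L
  for (start in seq.int(1L, nt, by = chunk)) {
    end <- min(nt, start + chunk - 1L)
    ntc <- end - start + 1L
    hits <- which(stats::runif(ns * ntc) < p)
    ci <- ci + 1L
    if (length(hits)) {
      s <- src_ids[((hits - 1L) %% ns) + 1L]
      tg <- tgt_ids[start + ((hits - 1L) %/% ns)]
      if (no_self) {
        keep <- s != tg
        s <- s[keep]; tg <- tg[keep]
      }
      acc_s[[ci]] <- s; acc_t[[ci]] <- tg
    }
  }
  list(src = unlist(acc_s, use.names = FALSE) %||% integer(0),
       tgt = unlist(acc_t, use.names = FALSE) %||% integer(0))
}

# Fixed in-degree sampling: every target receives exactly k distinct afferents.
.fixed_indegree_edges <- function(src_ids, tgt_ids, k, no_self = FALSE) {
  if (k == 0L || length(tgt_ids) == 0L)
    return(list(src = integer(0), tgt = integer(0)))
  src <- integer(k * length(tgt_ids))
  pos <- 0L
  for (tg in tgt_ids) {
    cand <- if (no_self) src_ids[src_ids != tg] else src_ids
    if (k > length(cand))
      stop("infeasible in-degree: ", k, " afferents requested from ",
           length(cand), " candidates")
    src[pos + seq_len(k)] <- cand[sample.int(length(cand), k)]
    pos <- pos + k
  }
  list(src = src, tgt = rep(tgt_ids, each = k))
}

.csr <- function(src, tgt, w, n) {
  o <- order(src, method = "radix")
  list(ptr = c(0L, cumsum(tabulate(src, nbins = n))),
       tgt = tgt[o], w = w[o])
}

#' Build a network connectome with an embedded assembly sequence
#'
#' Samples all synapses of the configured variant: sequence recurrent
#' (within-assembly) and feedforward (to the next assembly) projections with
#' probabilities \code{p_r} and \code{p_f}, plus the variant's background /
#' inhibitory / Poisson projections. In the \code{ei_assemblies} variant the
#' recurrent probability applies to all pairs of assembly members (E and I
#' alike); feedforward connections are always E-to-E. All I-to-E synapses are
#' plastic and start at \code{g0_EI}. In \code{fixed_in_degree} mode every
#' sequence neuron receives exactly \code{round(M*p_r)} recurrent and
#' \code{round(M*p_f)} feedforward afferents; other projections stay
#' Bernoulli.
#'
#' Neuron ids: excitatory cells come first (assembly i occupies ids
#' \code{((i-1)M+1):(iM)}), inhibitory cells follow.
#'
#' @param config A \code{"network_config"}.
#' @param p_r Recurrent connection probability.
#' @param p_f Feedforward connection probability.
#' @param seed Integer seed (the build is reproducible given the seed).
#' @return An object of class \code{"connectome"}.
#' @export
buildConnectome <- function(config, p_r, p_f, seed) {
  stopifnot(inherits(config, "network_config"),
            p_r >= 0, p_r <= 1, p_f >= 0, p_f <= 1)
  set.seed(seed)
  cfg <- config
  n_E <- cfg$N_E; n_I <- cfg$N_I; n <- n_E + n_I
  M <- cfg$M; q <- cfg$q
  fixed <- cfg$connectivity_mode == "fixed_in_degree"

  assembly <- integer(n)
  for (i in seq_len(q)) assembly[((i - 1L) * M + 1L):(i * M)] <- i
  is_inh <- c(rep(FALSE, n_E), rep(TRUE, n_I))
  Mi <- 0L
  if (cfg$model_variant == "ei_assemblies") {
    Mi <- M %/% 4L
    for (i in seq_len(q)) assembly[n_E + ((i - 1L) * Mi + 1L):(i * Mi)] <- i
  }

  es <- et <- list(); ew <- list()   # excitatory conductance synapses (-> gE)
  is_ <- it <- list()                # static inhibitory (I->I, -> gI)
  ps <- pt <- list()                 # plastic I->E (-> gI)
  add_exc <- function(e, w) {
    if (length(e$src)) {
      k <- length(es) + 1L
      es[[k]] <<- e$src; et[[k]] <<- e$tgt
      ew[[k]] <<- rep(w, length(e$src))
    }
  }
  add_inh <- function(e) {
    if (length(e$src)) { k <- length(is_) + 1L; is_[[k]] <<- e$src; it[[k]] <<- e$tgt }
  }
  add_pla <- function(e) {
    if (length(e$src)) { k <- length(ps) + 1L; ps[[k]] <<- e$src; pt[[k]] <<- e$tgt }
  }

  seq_edges <- function(src_mem, tgt_mem, p, recurrent) {
    if (fixed) .fixed_indegree_edges(src_mem, tgt_mem, as.integer(round(M * p)),
                                     no_self = recurrent)
    else .bernoulli_edges(src_mem, tgt_mem, p, no_self = recurrent)
  }

  # sequence projections (E -> E)
  for (i in seq_len(q)) {
    mem <- which(assembly == i & !is_inh)
    add_exc(seq_edges(mem, mem, p_r, TRUE), cfg$g_EE)
    if (i < q) {
      nxt <- which(assembly == i + 1L & !is_inh)
      add_exc(seq_edges(mem, nxt, p_f, FALSE), cfg$g_EE)
    }
  }

  E_ids <- seq_len(n_E)
  I_ids <- if (n_I > 0L) n_E + seq_len(n_I) else integer(0)

  if (cfg$model_variant == "ei_assemblies") {
    # within-assembly EI projections with probability p_r
    for (i in seq_len(q)) {
      memE <- which(assembly == i & !is_inh)
      memI <- which(assembly == i & is_inh)
      add_exc(.bernoulli_edges(memE, memI, p_r), cfg$g_IE)
      add_inh(.bernoulli_edges(memI, memI, p_r, no_self = TRUE))
      add_pla(.bernoulli_edges(memI, memE, p_r))
    }
    # background connections among all cells
    add_exc(.bernoulli_edges(E_ids, E_ids, cfg$p_bg, no_self = TRUE), cfg$g_EE)
    add_exc(.bernoulli_edges(E_ids, I_ids, cfg$p_bg), cfg$g_IE)
    add_inh(.bernoulli_edges(I_ids, I_ids, cfg$p_bg, no_self = TRUE))
    add_pla(.bernoulli_edges(I_ids, E_ids, cfg$p_bg))
  } else if (cfg$model_variant == "global_inhibition") {
    add_exc(.bernoulli_edges(E_ids, E_ids, cfg$p_bg, no_self = TRUE), cfg$g_EE)
    add_exc(.bernoulli_edges(E_ids, I_ids, cfg$p_IE), cfg$g_IE)
    add_inh(.bernoulli_edges(I_ids, I_ids, cfg$p_II, no_self = TRUE))
    add_pla(.bernoulli_edges(I_ids, E_ids, cfg$p_EI))
  }

  # external Poisson units
  poisson <- if (cfg$N_P > 0L)
    .bernoulli_edges(seq_len(cfg$N_P), E_ids, cfg$p_EP)
  else list(src = integer(0), tgt = integer(0))

  exc_src <- unlist(es, use.names = FALSE) %||% integer(0)
  exc <- .csr(exc_src, unlist(et, use.names = FALSE) %||% integer(0),
              unlist(ew, use.names = FALSE) %||% numeric(0), n)
  inh_src <- unlist(is_, use.names = FALSE) %||% integer(0)
  inh <- .csr(inh_src, unlist(it, use.names = FALSE) %||% integer(0),
              rep(cfg$g_II, length(inh_src)), n)
  pla_src <- unlist(ps, use.names = FALSE) %||% integer(0)
  pla_tgt <- unlist(pt, use.names = FALSE) %||% integer(0)
  pla <- .csr(pla_src, pla_tgt, rep(cfg$g0_EI, length(pla_src)), n)
  # CSC view of the plastic projection (by target), indices into pla$w
  po <- order(pla_src, method = "radix")
  tgt_sorted <- pla$tgt
  co <- order(tgt_sorted, method = "radix")
  cptr <- c(0L, cumsum(tabulate(tgt_sorted, nbins = n)))
  csrc <- pla_src[po][co]
  cidx <- co
  qcsr <- .csr(poisson$src, poisson$tgt,
               numeric(length(poisson$src)), max(cfg$N_P, 1L))

  structure(list(
    n = n, n_E = n_E, n_I = n_I,
    assembly = assembly, is_inh = is_inh, M_I = Mi,
    exc = exc, inh = inh,
    plastic = list(ptr = pla$ptr, tgt = pla$tgt, w = pla$w,
                   cptr = cptr, csrc = csrc, cidx = cidx),
    poisson = list(ptr = qcsr$ptr, tgt = qcsr$tgt),
    config = cfg, p_r = p_r, p_f = p_f, seed = as.integer(seed)),
    class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %s, n = %d (E %d / I %d), p_r = %g, p_f = %g, seed = %d\n",
              x$config$model_variant, x$n, x$n_E, x$n_I, x$p_r, x$p_f, x$seed))
  cat(sprintf("  synapses: %d excitatory, %d static inhibitory, %d plastic I->E, %d Poisson\n",
              length(x$exc$tgt), length(x$inh$tgt), length(x$plastic$tgt),
              length(x$poisson$tgt)))
  invisible(x)
}

#' In-degrees of sequence neurons for a given projection
#'
#' Counts, for every neuron of assembly 2..q (feedforward) or 1..q
#' (recurrent), its number of afferent synapses from the corresponding
#' source assembly.
#'
#' @param connectome A \code{"connectome"}.
#' @param projection \code{"recurrent"} or \code{"feedforward"}.
#' @return Integer vector of in-degrees.
#' @export
sequenceInDegree <- function(connectome, projection = c("recurrent", "feedforward")) {
  projection <- match.arg(projection)
  cn <- connectome
  src_of <- function(e_ptr, k) findInterval(k - 1L, e_ptr[-1L]) + 1L
  # reconstruct sources from CSR
  nsyn <- length(cn$exc$tgt)
  src <- rep.int(seq_len(cn$n), diff(cn$exc$ptr))
  tgt <- cn$exc$tgt
  keep <- !cn$is_inh[src] & !cn$is_inh[tgt] & cn$assembly[src] > 0L & cn$assembly[tgt] > 0L
  src <- src[keep]; tgt <- tgt[keep]
  off <- if (projection == "recurrent") 0L else 1L
  sel <- cn$assembly[tgt] == cn$assembly[src] + off
  tgt_ids <- if (off == 0L) which(cn$assembly > 0L & !cn$is_inh)
             else which(cn$assembly > 1L & !cn$is_inh)
  tabulate(tgt[sel], nbins = cn$n)[tgt_ids]
}
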