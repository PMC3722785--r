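#' Rate-coded network substrate
#'
#' A deliberately minimal stand-in for a full biologically detailed framework:
#' layers of units with activations in \[0, 1\], weighted bidirectional
#' projections, hard k-winners-take-all inhibition, and synchronous settling
#' to attractor states. Three local learning rules operate on projection
#' weights: Hebbian (CPCA-style), contrastive error-driven (plus/minus
#' phases), and dopamine-modulated three-factor updates.
#'
#' @name substrate
NULL

#' Create a network layer
#'
#' @param name Layer identifier (unique within a network).
#' @param n Number of units.
#' @param k Number of k-winners-take-all winners, `1 <= k <= n`. `k = n`
#'   disables competition.
#' @param gain Slope of the logistic activation function (> 0).
#' @param clamped If `TRUE` the layer's activations are fixed to a clamp
#'   pattern and never overwritten by settling.
#' @param k_start,k_ramp_cycles Optional inhibition schedule: competition
#'   starts loose at `k_start` winners and tightens linearly to `k` over
#'   `k_ramp_cycles` settling cycles. Used to make early broad activation
#'   observable before a single winner emerges.
#'
#' @return A `cogseq_layer` list.
#' @export
layer_spec <- function(name, n, k = n, gain = 5, clamped = FALSE,
                       k_start = NULL, k_ramp_cycles = 0L) {
  stopifnot(is.character(name), length(name) == 1L, n >= 1L)
  if (k < 1L || k > n) {
    stop("layer '", name, "': k must satisfy 1 <= k <= n", call. = FALSE)
  }
  if (!is.null(k_start) && (k_start < k || k_start > n)) {
    stop("layer '", name, "': k_start must satisfy k <= k_start <= n",
         call. = FALSE)
  }
  structure(
    list(name = name, n = as.integer(n), act = numeric(n),
         k = as.integer(k), gain = gain, clamped = clamped,
         clamp_pattern = NULL,
         k_start = if (is.null(k_start)) NULL else as.integer(k_start),
         k_ramp_cycles = as.integer(k_ramp_cycles)),
    class = "cogseq_layer"
  )
}

#' Create a projection between layers
#'
#' @param src,dst Source and destination layer names.
#' @param W Weight matrix of shape `(dst_n, src_n)` with entries in \[0, 1\].
#' @param scale Relative net-input scale (>= 0), constant during a settle.
#' @param rule Learning rule tag: one of `"hebbian"`, `"error_driven"`,
#'   `"three_factor"`, `"fixed"`. Informational for [train_triads()]-style
#'   loops; the update functions themselves are rule-specific.
#'
#' @return A `cogseq_projection` list.
#' @export
projection_spec <- function(src, dst, W, scale = 1,
                            rule = c("fixed", "hebbian", "error_driven",
                                     "three_factor")) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(W), scale >= 0, all(is.finite(W)))
  if (any(W < 0 | W > 1)) {
    stop("projection ", src, "->", dst, ": weights must lie in [0, 1]",
         call. = FALSE)
  }
  structure(list(src = src, dst = dst, W = W, scale = scale, rule = rule),
            class = "cogseq_projection")
}

#' Random initial weights
#'
#' Uniform in \[0.25, 0.75\], the conventional mid-range start that leaves
#' room for both potentiation and depression under \[0, 1\] clipping.
#'
#' @param n_dst,n_src Matrix dimensions (rows = destination units).
#' @return A weight matrix.
#' @export
init_weights <- function(n_dst, n_src) {
  matrix(stats::runif(n_dst * n_src, 0.25, 0.75), nrow = n_dst, ncol = n_src)
}

#' Assemble a network
#'
#' @param layers List of [layer_spec()] objects.
#' @param projections List of [projection_spec()] objects.
#' @param max_cycles Settling cycle budget (default 100).
#' @param tol Convergence tolerance on the maximum per-unit activation change
#'   in one cycle (default 0.005).
#' @param step Per-cycle step rate toward the instantaneous activation target
#'   (default 0.3); smooth trajectories keep the phases of settling
#'   observable.
#'
#' @return A `cogseq_network` list.
#' @export
network_spec <- function(layers, projections = list(), max_cycles = 100L,
                         tol = 0.005, step = 0.3) {
  stopifnot(tol > 0, max_cycles >= 1L, step > 0, step <= 1)
  nms <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate layer names", call. = FALSE)
  names(layers) <- nms
  for (p in projections) {
    if (!p$src %in% nms || !p$dst %in% nms) {
      stop("projection ", p$src, "->", p$dst, " references unknown layer",
           call. = FALSE)
    }
    if (ncol(p$W) != layers[[p$src]]$n || nrow(p$W) != layers[[p$dst]]$n) {
      stop("projection ", p$src, "->", p$dst, ": weight matrix shape ",
           nrow(p$W), "x", ncol(p$W), " does not match layer sizes",
           call. = FALSE)
    }
  }
  structure(
    list(layers = layers, projections = projections,
         max_cycles = as.integer(max_cycles), tol = tol, step = step),
    class = "cogseq_network"
  )
}

#' Net input to a layer
#'
#' Sums `scale * W %*% src_act` over all incoming projections and divides by
#' the number of incoming projections, so adding a projection rebalances
#' rather than inflates total drive.
#'
#' @param net A `cogseq_network`.
#' @param layer_name Destination layer.
#' @param acts Named list of activation vectors, one per layer.
#' @return Net-input vector of length `layer$n`.
#' @export
compute_net_input <- function(net, layer_name, acts) {
  lay <- net$layers[[layer_name]]
  total <- numeric(lay$n)
  n_in <- 0L
  for (p in net$projections) {
    if (p$dst != layer_name) next
    src_act <- acts[[p$src]]
    if (length(src_act) != ncol(p$W)) {
      stop("projection ", p$src, "->", p$dst, ": dimension mismatch",
           call. = FALSE)
    }
    total <- total + p$scale * as.numeric(p$W %*% src_act)
    n_in <- n_in + 1L
  }
  if (n_in > 0L) total <- total / n_in
  if (!all(is.finite(total))) {
    stop("non-finite net input in layer ", layer_name, call. = FALSE)
  }
  total
}

#' k-winners-take-all inhibition threshold
#'
#' Places the inhibition level at the midpoint between the k-th and (k+1)-th
#' largest net inputs, so exactly the top k units receive positive drive
#' whenever those order statistics differ. `k = n` returns `min(net)` minus a
#' small epsilon so nothing is suppressed.
#'
#' @param net_input Net-input vector.
#' @param k Winner count, `1 <= k <= length(net_input)`.
#' @return Scalar inhibition threshold.
#' @export
kwta_threshold <- function(net_input, k) {
  n <- length(net_input)
  if (k < 1L || k > n) stop("k must satisfy 1 <= k <= n", call. = FALSE)
  if (k == n) return(min(net_input) - 1e-6)
  srt <- sort(net_input, decreasing = TRUE)
  (srt[k] + srt[k + 1L]) / 2
}

#' Logistic unit activation
#'
#' Saturating monotone sigmoid: `1 / (1 + exp(-gain * drive))`. Value 0.5 at
#' zero drive; approaches 0 and 1 in the limits.
#'
#' @param drive Net input minus inhibition.
#' @param gain Slope (> 0), default 5.
#' @return Activation in \[0, 1\].
#' @export
activation_fn <- function(drive, gain = 5) {
  stopifnot(all(is.finite(drive)))
  1 / (1 + exp(-gain * drive))
}

kwta_k_at_cycle <- function(lay, cycle) {
  if (is.null(lay$k_start) || lay$k_ramp_cycles <= 0L) return(lay$k)
  frac <- min(1, (cycle - 1L) / lay$k_ramp_cycles)
  as.integer(round(lay$k_start + frac * (lay$k - lay$k_start)))
}

#' Settle a network to an attractor
#'
#' Synchronous cycles of net input -> kWTA inhibition -> logistic activation,
#' moving each unit a fraction `step` toward its instantaneous target per
#' cycle, until the maximum per-unit change falls below `tol` or the cycle
#' budget runs out. Clamped layers are never overwritten.
#'
#' @param net A `cogseq_network`.
#' @param clamps Named list mapping layer name to a clamp pattern (length
#'   `layer$n`, values in \[0, 1\]). Clamped layers hold that pattern exactly.
#' @param init Optional named list of initial activations for unclamped
#'   layers (default: all zeros).
#' @param trace If `TRUE`, record per-cycle activation snapshots.
#' @return A `cogseq_settle` list: `final_act` (named list), `cycles_run`,
#'   `converged`, and (optionally) `trace`, a tibble with columns cycle,
#'   layer, unit, act.
#' @export
settle <- function(net, clamps = list(), init = NULL, trace = FALSE) {
  acts <- lapply(net$layers, function(l) numeric(l$n))
  clamped <- character(0)
  for (nm in names(clamps)) {
    if (!nm %in% names(net$layers)) stop("unknown layer '", nm, "'", call. = FALSE)
    pat <- clamps[[nm]]
    if (length(pat) != net$layers[[nm]]$n) {
      stop("clamp for '", nm, "' has wrong length", call. = FALSE)
    }
    acts[[nm]] <- pat
    clamped <- c(clamped, nm)
  }
  for (nm in names(init)) {
    if (!nm %in% clamped) acts[[nm]] <- init[[nm]]
  }
  free <- setdiff(names(net$layers), clamped)
  snapshots <- if (trace) vector("list", net$max_cycles) else NULL

  cycles <- 0L
  converged <- FALSE
  for (cyc in seq_len(net$max_cycles)) {
    cycles <- cyc
    new_acts <- acts
    max_delta <- 0
    for (nm in free) {
      lay <- net$layers[[nm]]
      ni <- compute_net_input(net, nm, acts)
      thr <- kwta_threshold(ni, kwta_k_at_cycle(lay, cyc))
      target <- activation_fn(ni - thr, lay$gain)
      upd <- acts[[nm]] + net$step * (target - acts[[nm]])
      if (!all(is.finite(upd))) {
        stop("non-finite activation in layer ", nm, " at cycle ", cyc,
             call. = FALSE)
      }
      upd <- pmin(1, pmax(0, upd))
      max_delta <- max(max_delta, max(abs(upd - acts[[nm]])))
      new_acts[[nm]] <- upd
    }
    acts <- new_acts
    if (cyc == 1L) {
      # convergence may not pre-empt an unfinished inhibition ramp
      min_cycles <- max(c(1L, vapply(net$layers, function(l)
        if (is.null(l$k_start)) 1L else l$k_ramp_cycles, integer(1))))
    }
    if (trace) {
      snapshots[[cyc]] <- tibble::tibble(
        cycle = cyc,
        layer = rep(names(acts), vapply(acts, length, integer(1))),
        unit = unlist(lapply(acts, seq_along), use.names = FALSE) - 1L,
        act = unlist(acts, use.names = FALSE)
      )
    }
    if (max_delta < net$tol && cyc >= min_cycles) {
      converged <- TRUE
      break
    }
  }

  structure(
    list(final_act = acts, cycles_run = cycles, converged = converged,
         trace = if (trace) dplyr::bind_rows(snapshots[seq_len(cycles)])),
    class = "cogseq_settle"
  )
}

clip01 <- function(W) {
  W[W < 0] <- 0
  W[W > 1] <- 1
  W
}

#' Hebbian (CPCA-style) weight update
#'
#' `dW[i, j] = lr * post[i] * (pre[j] - W[i, j])`: weights move toward the
#' presynaptic activation in proportion to postsynaptic activity, so under
#' repeated pairing of a fixed pattern each active row converges
#' geometrically onto the presynaptic pattern.
#'
#' @param pre_act,post_act Pre- and postsynaptic activation vectors.
#' @param W Weight matrix `(post, pre)`.
#' @param lr Learning rate (> 0), default 0.04.
#' @return Updated weight matrix, clipped to \[0, 1\].
#' @export
hebbian_update <- function(pre_act, post_act, W, lr = 0.04) {
  stopifnot(lr > 0, length(post_act) == nrow(W), length(pre_act) == ncol(W))
  # dw_ij = lr * post_i * (pre_j - w_ij)
  dW <- lr * (outer(post_act, pre_act) - W * post_act)
  clip01(W + dW)
}

#' Contrastive error-driven weight update
#'
#' Two-phase rule: the plus phase has the correct answer clamped, the minus
#' phase is the network's own response. `dW = lr * (post+ pre+' - post- pre-')`
#' drives weights until the free response matches the clamped one — a local
#' error-driven rule that needs no backpropagated gradients.
#'
#' @param pre_minus,post_minus Minus-phase (free) activations.
#' @param pre_plus,post_plus Plus-phase (clamped) activations.
#' @param W Weight matrix `(post, pre)`.
#' @param lr Learning rate, default 0.04.
#' @return Updated weight matrix, clipped to \[0, 1\].
#' @export
error_driven_update <- function(pre_minus, post_minus, pre_plus, post_plus,
                                W, lr = 0.04) {
  if (length(pre_minus) != length(pre_plus) ||
      length(post_minus) != length(post_plus)) {
    stop("plus and minus phases have mismatched shapes", call. = FALSE)
  }
  stopifnot(length(post_plus) == nrow(W), length(pre_plus) == ncol(W))
  dW <- lr * (outer(post_plus, pre_plus) - outer(post_minus, pre_minus))
  clip01(W + dW)
}

#' Dopamine-modulated three-factor update
#'
#' `dW[i, j] = lr * pathway_sign * da * post[i] * pre[j]`, the striatal
#' learning rule: co-active pre/post pairs are potentiated on dopamine bursts
#' and depressed on dips (Go pathway, `pathway_sign = +1`), with the opposite
#' sign for the NoGo pathway. `eligibility` masks the update to the units
#' that took part in the most recent gating event.
#'
#' @param pre_act,post_act Activation vectors at the gated event.
#' @param da Dopamine scalar (burst > 0, dip < 0).
#' @param W Weight matrix `(post, pre)`.
#' @param lr Learning rate, default 0.1.
#' @param pathway_sign `+1` (Go) or `-1` (NoGo).
#' @param eligibility Optional 0/1 matrix of the same shape as `W`
#'   (default: all eligible).
#' @return Updated weight matrix, clipped to \[0, 1\].
#' @export
three_factor_update <- function(pre_act, post_act, da, W, lr = 0.1,
                                pathway_sign = 1, eligibility = NULL) {
  stopifnot(is.finite(da), pathway_sign %in% c(-1, 1))
  dW <- lr * pathway_sign * da * outer(post_act, pre_act)
  if (!is.null(eligibility)) dW <- dW * eligibility
  clip01(W + dW)
}

#' @export
print.cogseq_network <- function(x, ...) {
  cat("<cogseq_network> ", length(x$layers), " layers, ",
      length(x$projections), " projections\n", sep = "")
  for (l in x$layers) {
    cat("  layer ", l$name, ": n=", l$n, " k=", l$k,
        if (l$clamped) " (clamped)" else "", "\n", sep = "")
  }
  invisible(x)
}

#' Export a settling trace as a cycle/layer/unit/act table
#'
#' @param result A `cogseq_settle` with a recorded trace.
#' @param path Optional CSV path; if given the table is also written there.
#' @return The trace tibble, invisibly if written to `path`.
#' @export
settle_trace <- function(result, path = NULL) {
  if (is.null(result$trace)) stop("settle() was run without trace = TRUE", call. = FALSE)
  if (!is.null(path)) {
    utils::write.csv(result$trace, path, row.names = FALSE)
    return(invisible(result$trace))
  }
  result$trace
}
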