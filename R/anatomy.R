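#' Two-dimensional grid layout on a physical cortical patch
#'
#' Populations of different sizes covering the same patch get proportionally
#' different spacing, so a 60x60 excitatory grid and a 30x30 inhibitory grid
#' both span the same simulated 2 mm x 2 mm region.  Neuron `id` maps to grid
#' position column-major: `id = row + (col-1)*rows`.
#'
#' @param rows,cols grid dimensions
#' @param extent physical side length of the square patch (mm)
#' @return object of class `grid_layout` with fields `rows`, `cols`, `n`,
#'   `extent`, `spacing` (mm per grid step) and an `n x 2` matrix `pos` of
#'   physical positions (mm)
#' @export
grid_layout <- function(rows, cols = rows, extent = 2) {
  stopifnot(rows >= 1, cols >= 1, extent > 0)
  xs <- (seq_len(cols) - 0.5) * extent / cols
  ys <- (seq_len(rows) - 0.5) * extent / rows
  pos <- cbind(x = rep(xs, each = rows), y = rep(ys, times = cols))
  structure(list(rows = rows, cols = cols, n = rows * cols, extent = extent,
                 spacing = extent / max(rows, cols), pos = pos),
            class = "grid_layout")
}

# Sample a projection: for each postsynaptic neuron, Bernoulli draws over all
# candidate sources with probability proportional to `prob_fun(distance)`,
# rescaled so the expected in-degree equals n_syn.  Initial weights come from
# `weight_fun(distance)` and are scaled per neuron to sum to s_total
# (clip-scale-clip against s_max).  Non-periodic boundaries: probability mass
# falling outside the grid is simply lost before rescaling.
sample_projection <- function(pre, post, prob_fun, weight_fun, n_syn,
                              s_total = 1, s_max = Inf,
                              exclude_self = FALSE) {
  n_pre <- pre$n
  pre_l <- vector("list", post$n)
  w_l <- vector("list", post$n)
  post_l <- vector("list", post$n)
  px <- pre$pos[, 1]; py <- pre$pos[, 2]
  for (i in seq_len(post$n)) {
    d <- sqrt((px - post$pos[i, 1])^2 + (py - post$pos[i, 2])^2)
    praw <- prob_fun(d)
    if (exclude_self) praw[i] <- 0
    tot <- sum(praw)
    n_cand <- sum(praw > 0)
    if (n_cand == 0)
      stop("no candidate sources for neuron ", i,
           " (empty annulus or overly strict rule)")
    if (n_syn > n_cand)
      stop("requested in-degree ", n_syn, " exceeds the ", n_cand,
           " candidate sources of neuron ", i)
    p <- pmin(praw * n_syn / tot, 1)
    sel <- which(runif(n_pre) < p)
    if (!length(sel)) next
    w <- weight_fun(d[sel], length(sel))
    w <- pmin(pmax(w, 0), s_max)
    if (sum(w) > 0) w <- pmin(w * s_total / sum(w), s_max)
    pre_l[[i]] <- sel
    post_l[[i]] <- rep.int(i, length(sel))
    w_l[[i]] <- w
  }
  list(pre = unlist(pre_l), post = unlist(post_l),
       weight = unlist(w_l), n_pre = n_pre, n_post = post$n)
}

finish_projection <- function(wiring, rule, params) {
  structure(c(wiring, list(rule = rule, rule_params = params)),
            class = "cas_projection")
}

#' Local Gaussian connectivity
#'
#' Connection probability to each candidate source falls off as a
#' two-dimensional Gaussian of the distance, scaled so the expected
#' in-degree is `n_syn`.  Initial weights follow the same Gaussian of
#' distance and are normalized per neuron to `s_total`.
#'
#' @param pre,post [grid_layout()]s of the source and target populations
#' @param sigma Gaussian standard deviation (mm)
#' @param n_syn expected number of synapses per postsynaptic neuron
#' @param s_total initial incoming weight sum per neuron (nS)
#' @param s_max per-synapse cap (nS)
#' @param exclude_self drop self-connections (use when `pre` and `post` are
#'   the same population)
#' @param seed optional RNG seed for reproducible wiring
#' @return a `cas_projection`: vectors `pre`, `post`, `weight` plus metadata
#' @export
build_local_gaussian <- function(pre, post, sigma, n_syn, s_total = 1,
                                 s_max = Inf, exclude_self = FALSE,
                                 seed = NULL) {
  stopifnot(sigma > 0, n_syn >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- function(d) exp(-d^2 / (2 * sigma^2))
  wiring <- sample_projection(pre, post, g, function(d, n) g(d), n_syn,
                              s_total, s_max, exclude_self)
  finish_projection(wiring, "local_gaussian",
                    list(sigma = sigma, n_syn = n_syn, s_total = s_total))
}

#' Annular-surround connectivity
#'
#' Sources are restricted to an annulus `r_min <= d <= r_max` around each
#' target; both the connection probability and the initial weight follow a
#' Gaussian of distance centered at `(r_min + r_max)/2` with spread `sigma`.
#'
#' @inheritParams build_local_gaussian
#' @param r_min,r_max inner and outer annulus radii (mm)
#' @export
build_annular <- function(pre, post, r_min, r_max, sigma, n_syn,
                          s_total = 1, s_max = Inf, exclude_self = FALSE,
                          seed = NULL) {
  stopifnot(r_min >= 0, r_max > r_min, sigma > 0, n_syn >= 1)
  if (!is.null(seed)) set.seed(seed)
  mid <- (r_min + r_max) / 2
  g <- function(d) ifelse(d >= r_min & d <= r_max,
                          exp(-(d - mid)^2 / (2 * sigma^2)), 0)
  wiring <- sample_projection(pre, post, g, function(d, n) g(d), n_syn,
                              s_total, s_max, exclude_self)
  finish_projection(wiring, "annular",
                    list(r_min = r_min, r_max = r_max, sigma = sigma,
                         n_syn = n_syn, s_total = s_total))
}

#' Uniform random connectivity
#'
#' Every candidate source is equally likely; initial weights are drawn
#' uniformly and normalized per neuron to `s_total`.
#'
#' @inheritParams build_local_gaussian
#' @export
build_uniform_random <- function(pre, post, n_syn, s_total = 1, s_max = Inf,
                                 exclude_self = FALSE, seed = NULL) {
  stopifnot(n_syn >= 1)
  if (!is.null(seed)) set.seed(seed)
  wiring <- sample_projection(pre, post, function(d) rep(1, length(d)),
                              function(d, n) runif(n, 0.5, 1.5), n_syn,
                              s_total, s_max, exclude_self)
  finish_projection(wiring, "uniform_random",
                    list(n_syn = n_syn, s_total = s_total))
}

#' Topographically limited random connectivity
#'
#' Uniform random connectivity restricted to sources whose retinotopic
#' position lies within `max_radius` of the target's position; gives the
#' input pathway a rough initial topographic bias.  `max_radius = Inf`
#' reduces to [build_uniform_random()].
#'
#' @inheritParams build_local_gaussian
#' @param max_radius maximum source-to-target distance (mm)
#' @export
build_topographic_limited <- function(pre, post, max_radius, n_syn,
                                      s_total = 1, s_max = Inf,
                                      seed = NULL) {
  stopifnot(max_radius > 0, n_syn >= 1)
  if (!is.null(seed)) set.seed(seed)
  wiring <- sample_projection(pre, post,
                              function(d) as.numeric(d <= max_radius),
                              function(d, n) runif(n, 0.5, 1.5), n_syn,
                              s_total, s_max, FALSE)
  finish_projection(wiring, "topographic_limited",
                    list(max_radius = max_radius, n_syn = n_syn,
                         s_total = s_total))
}

#' Default structural parameters of the cortical sheet
#'
#' Local Gaussian spread and in-degree for excitatory axons, annulus
#' geometry for inhibitory axons, thalamic in-degree, and the enlarged
#' inhibitory sigma used by the control center-surround architecture.
#' All tunable.
#'
#' @return named list of structural parameters
#' @export
structure_defaults <- function() {
  list(sigma_local = 0.2, n_syn_local = 50,
       r_min = 0.3, r_max = 2.9, sigma_annulus = 0.8, n_syn_annulus = 50,
       n_syn_thal = 20, sigma_cs_inh = 0.5,
       thal_rule = "uniform", thal_radius = 0.65)
}

#' Synaptic gain defaults
#'
#' NMDA/AMPA conductance ratio (below one, as measured in cortex), the
#' GABA-B/GABA-A ratio, and the slow-hyperpolarizing gain (zero outside the
#' visuomotor experiment).
#'
#' @return named list
#' @export
gain_defaults <- function() {
  list(nmda_gain = 0.2, gabab_gain = 0.05, gabash_gain = 0)
}

attach_pathway <- function(proj, src, dst, src_class, dst_class, s_total,
                           s_max, gains, plastic = FALSE, alpha = 0) {
  stp <- stp_pathway_params(src_class, dst_class)
  proj$src <- src
  proj$dst <- dst
  proj$inhibitory <- src_class == "inhibitory"
  proj$nmda_gain <- gains$nmda_gain
  proj$gabab_gain <- gains$gabab_gain
  proj$gabash_gain <- gains$gabash_gain
  proj$tau_x <- stp$tau_x
  proj$p <- stp$p
  proj$plastic <- plastic
  proj$alpha <- alpha
  proj$s_total <- s_total
  proj$s_max <- s_max
  proj
}

#' Build a full network in one of the four studied architectures
#'
#' * `cas`: excitatory axons project locally (Gaussian) to both cortical
#'   populations; inhibitory axons project to an annular surround of both.
#' * `center_surround`: all pathways Gaussian, inhibition with a larger
#'   sigma than excitation.
#' * `inverse`: excitatory axons annular, inhibitory axons local.
#' * `random`: uniform random connectivity on all four cortical pathways.
#'
#' Thalamic input is uniform random to both cortical populations (or
#' topographically limited when `struct$thal_rule == "topographic"`).
#'
#' @param architecture one of `"cas"`, `"center_surround"`, `"inverse"`,
#'   `"random"`
#' @param exc,inh,thal grid dimensions `c(rows, cols)` of the three
#'   populations
#' @param couplings named list of incoming-sum targets (nS) per pathway:
#'   `ee`, `ei`, `ie`, `ii`, `te`, `ti`
#' @param extent side of the simulated cortical patch (mm)
#' @param struct structural parameters, see [structure_defaults()]
#' @param gains receptor gain ratios, see [gain_defaults()]
#' @param s_max per-synapse cap (nS)
#' @param seed RNG seed controlling the stochastic wiring
#' @return object of class `cas_network` with `populations` and
#'   `projections` (named `ee`, `ei`, `ie`, `ii`, `te`, `ti`)
#' @export
make_architecture <- function(architecture = c("cas", "center_surround",
                                               "inverse", "random"),
                              exc = c(59, 59), inh = c(30, 30),
                              thal = c(22, 22),
                              couplings = list(ee = 50, ei = 50, ie = 50,
                                               ii = 120, te = 20, ti = 20),
                              extent = 2, struct = structure_defaults(),
                              gains = gain_defaults(), s_max = Inf,
                              seed = NULL) {
  architecture <- match.arg(architecture)
  if (!is.null(seed)) set.seed(seed)
  le <- grid_layout(exc[1], exc[2], extent)
  li <- grid_layout(inh[1], inh[2], extent)
  lt <- grid_layout(thal[1], thal[2], extent)
  pops <- list(
    exc = list(name = "exc", class = "excitatory", layout = le,
               params = neuron_params("excitatory")),
    inh = list(name = "inh", class = "inhibitory", layout = li,
               params = neuron_params("inhibitory")),
    thal = list(name = "thal", class = "thalamic", layout = lt,
                params = neuron_params("thalamic")))

  ann_from <- function(pre, post, self) build_annular(
    pre, post, struct$r_min, struct$r_max, struct$sigma_annulus,
    struct$n_syn_annulus, exclude_self = self)

  wire <- switch(architecture,
    cas = list(
      ee = build_local_gaussian(le, le, struct$sigma_local,
                                struct$n_syn_local, exclude_self = TRUE),
      ei = build_local_gaussian(le, li, struct$sigma_local,
                                struct$n_syn_local),
      ie = ann_from(li, le, FALSE),
      ii = ann_from(li, li, TRUE)),
    center_surround = list(
      ee = build_local_gaussian(le, le, struct$sigma_local,
                                struct$n_syn_local, exclude_self = TRUE),
      ei = build_local_gaussian(le, li, struct$sigma_local,
                                struct$n_syn_local),
      ie = build_local_gaussian(li, le, struct$sigma_cs_inh,
                                struct$n_syn_annulus),
      ii = build_local_gaussian(li, li, struct$sigma_cs_inh,
                                struct$n_syn_annulus, exclude_self = TRUE)),
    inverse = list(
      ee = build_annular(le, le, struct$r_min, struct$r_max,
                         struct$sigma_annulus, struct$n_syn_local,
                         exclude_self = TRUE),
      ei = build_annular(le, li, struct$r_min, struct$r_max,
                         struct$sigma_annulus, struct$n_syn_local),
      ie = build_local_gaussian(li, le, struct$sigma_local,
                                struct$n_syn_annulus),
      ii = build_local_gaussian(li, li, struct$sigma_local,
                                struct$n_syn_annulus, exclude_self = TRUE)),
    random = list(
      ee = build_uniform_random(le, le, struct$n_syn_local,
                                exclude_self = TRUE),
      ei = build_uniform_random(le, li, struct$n_syn_local),
      ie = build_uniform_random(li, le, struct$n_syn_annulus),
      ii = build_uniform_random(li, li, struct$n_syn_annulus,
                                exclude_self = TRUE)))

  if (identical(struct$thal_rule, "topographic")) {
    wire$te <- build_topographic_limited(lt, le, struct$thal_radius,
                                         struct$n_syn_thal)
    wire$ti <- build_topographic_limited(lt, li, struct$thal_radius,
                                         struct$n_syn_thal)
  } else {
    wire$te <- build_uniform_random(lt, le, struct$n_syn_thal)
    wire$ti <- build_uniform_random(lt, li, struct$n_syn_thal)
  }

  cls <- c(exc = "excitatory", inh = "inhibitory", thal = "thalamic")
  ends <- list(ee = c("exc", "exc"), ei = c("exc", "inh"),
               ie = c("inh", "exc"), ii = c("inh", "inh"),
               te = c("thal", "exc"), ti = c("thal", "inh"))
  idx <- c(exc = 1, inh = 2, thal = 3)
  projections <- lapply(names(ends), function(nm) {
    en <- ends[[nm]]
    pr <- attach_pathway(wire[[nm]], idx[[en[1]]], idx[[en[2]]],
                         cls[[en[1]]], cls[[en[2]]],
                         s_total = couplings[[nm]], s_max = s_max, gains)
    # rescale initial weights to the pathway coupling target
    pr$weight <- scale_synapses(pr$weight, pr$post, pr$n_post,
                                couplings[[nm]], s_max)
    pr
  })
  names(projections) <- names(ends)
  structure(list(architecture = architecture, populations = pops,
                 projections = projections, couplings = couplings,
                 struct = struct, gains = gains, s_max = s_max),
            class = "cas_network")
}

#' @export
print.cas_network <- function(x, ...) {
  cat("<cas_network>", x$architecture, "architecture\n")
  for (p in x$populations)
    cat(sprintf("  %-5s %s  %dx%d (%d neurons)\n", p$name, p$class,
                p$layout$rows, p$layout$cols, p$layout$n))
  for (nm in names(x$projections)) {
    pr <- x$projections[[nm]]
    cat(sprintf("  %s: %s, %d synapses, s_total=%g\n", nm, pr$rule,
                length(pr$pre), pr$s_total))
  }
  invisible(x)
}

#' Export or import wiring as columnar text
#'
#' Writes one file with columns `pre_id`, `post_id`, `weight_nS` plus a JSON
#' header line (prefixed `#`) holding the rule and its parameters.
#'
#' @param projection a `cas_projection`
#' @param file path
#' @export
write_wiring <- function(projection, file) {
  hdr <- jsonlite::toJSON(list(rule = projection$rule,
                               params = projection$rule_params),
                          auto_unbox = TRUE)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  writeLines("pre_id\tpost_id\tweight_nS", con)
  utils::write.table(data.frame(projection$pre, projection$post,
                                projection$weight),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE)
}

#' @rdname write_wiring
#' @export
read_wiring <- function(file) {
  hdr <- jsonlite::fromJSON(sub("^# ", "", readLines(file, n = 1)))
  d <- utils::read.table(file, skip = 2, sep = "\t",
                         col.names = c("pre", "post", "weight"))
  structure(list(pre = d$pre, post = d$post, weight = d$weight,
                 n_pre = max(d$pre), n_post = max(d$post),
                 rule = hdr$rule, rule_params = hdr$params),
            class = "cas_projection")
}
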