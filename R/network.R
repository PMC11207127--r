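# Network geometry and connectivity: four one-dimensional layers (200 PY,
# 40 IN, 40 TC, 40 RE), the full projection set with receptor types,
# conductances and connection radii, and the Poisson miniature-EPSP drive
# that seeds each slow-oscillation cycle.

.layer_codes <- c(PY = 0L, IN = 1L, TC = 2L, RE = 3L)
.receptor_codes <- c(AMPA = 0L, NMDA = 1L, GABA_A = 2L, GABA_B = 3L)

#' Layer sizes of the thalamocortical network
#'
#' @param N cells per thalamic/interneuron layer; the PY layer has `5 N`.
#' @return named integer vector (PY, IN, TC, RE).
#' @export
network_geometry <- function(N = 40) {
  stopifnot(N >= 1)
  c(PY = 5L * as.integer(N), IN = as.integer(N), TC = as.integer(N),
    RE = as.integer(N))
}

#' Synaptic projection table
#'
#' Source layer, target layer, receptor, maximal conductance (uS) and
#' connection radius for every projection of the network, with the
#' depression flag of the intracortical synapses.
#'
#' @return data.frame, one row per (projection, receptor).
#' @export
projection_table <- function() {
  data.frame(
    src      = c("PY", "PY", "PY", "PY", "IN", "TC", "RE", "RE", "RE",
                 "TC", "TC", "PY", "PY"),
    tgt      = c("PY", "PY", "IN", "IN", "PY", "RE", "TC", "TC", "RE",
                 "PY", "IN", "TC", "RE"),
    receptor = c("AMPA", "NMDA", "AMPA", "NMDA", "GABA_A", "AMPA",
                 "GABA_A", "GABA_B", "GABA_A", "AMPA", "AMPA", "AMPA",
                 "AMPA"),
    g        = c(0.025, 0.0019, 0.055, 0.001, 0.055, 0.1,
                 0.05, 0.02, 0.05, 0.01, 0.01, 0.003, 0.0015),
    radius   = c(11, 11, 3, 3, 11, 17, 17, 17, 11, 21, 5, 21, 17),
    depress  = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
                 FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

# position of every cell of a layer on the fine (PY-scale) grid; cells of
# the N-sized layers sit at the centre of their group of five PY positions.
.fine_pos <- function(layer, sizes) {
  n <- sizes[[layer]]
  if (layer == "PY") seq_len(n) - 1 else 5 * (seq_len(n) - 1) + 2
}

#' Connection list for one projection
#'
#' Every target cell receives connections from all source cells within the
#' projection radius.  Distances are measured on the target layer's own
#' index grid when neither side is the PY layer; when the PY layer is
#' involved, distances are measured on the fine 200-cell grid, with each
#' cell of an N-sized layer placed at the centre of its group of five PY
#' positions (`mapping = "fine"`, the default).  `mapping = "coarse"`
#' instead measures all distances in coarse (N-grid) units with PY index
#' `p` at coarse coordinate `p/5`.  Boundaries are open (edge cells receive
#' fewer connections); self-connections are excluded within a layer.
#'
#' @param src,tgt layer names.
#' @param radius connection radius (index units, see above).
#' @param sizes named layer sizes ([network_geometry()]).
#' @param mapping `"fine"` or `"coarse"`.
#' @return data.frame with 1-based `src` and `tgt` cell indices.
#' @export
connect_radius <- function(src, tgt, radius, sizes = network_geometry(),
                           mapping = c("fine", "coarse")) {
  mapping <- match.arg(mapping)
  ns <- sizes[[src]]; nt <- sizes[[tgt]]
  if (mapping == "fine") {
    if (src != "PY" && tgt != "PY") {
      # no PY side: distances on the layers' own (N-sized) index grid
      ps <- seq_len(ns) - 1; pt <- seq_len(nt) - 1
    } else {
      ps <- .fine_pos(src, sizes); pt <- .fine_pos(tgt, sizes)
    }
  } else {
    ps <- if (src == "PY") (seq_len(ns) - 1) / 5 else seq_len(ns) - 1
    pt <- if (tgt == "PY") (seq_len(nt) - 1) / 5 else seq_len(nt) - 1
  }
  out_src <- integer(0); out_tgt <- integer(0)
  for (s in seq_len(ns)) {
    hit <- which(abs(pt - ps[s]) <= radius + 1e-9)
    if (src == tgt) hit <- hit[hit != s]
    out_src <- c(out_src, rep.int(s, length(hit)))
    out_tgt <- c(out_tgt, hit)
  }
  data.frame(src = out_src, tgt = out_tgt)
}

#' Build the network model
#'
#' Assembles layer sizes and the full connection lists of every projection.
#' Construction is deterministic given the geometry.
#'
#' @param N cells per non-PY layer.
#' @param mapping radius interpretation, see [connect_radius()].
#' @param projections projection table (defaults to [projection_table()];
#'   presets override the corticothalamic conductances here).
#' @return object of class `tc_network`: layer sizes and a list of
#'   projections, each with its connection list and receptor parameters.
#' @export
build_network <- function(N = 40, mapping = "fine",
                          projections = projection_table()) {
  sizes <- network_geometry(N)
  need <- c("src", "tgt", "receptor", "g", "radius", "depress")
  if (!all(need %in% names(projections)))
    stop("projection table must have columns ", paste(need, collapse = ", "))
  if (!all(projections$src %in% names(sizes)) ||
      !all(projections$tgt %in% names(sizes)))
    stop("unknown layer in projection table")
  plist <- lapply(seq_len(nrow(projections)), function(i) {
    row <- projections[i, ]
    conn <- connect_radius(row$src, row$tgt, row$radius, sizes, mapping)
    U <- if (row$receptor == "AMPA") 0.07 else
         if (row$receptor == "GABA_A") 0.073 else 0
    list(name = paste0(row$src, "->", row$tgt, " ", row$receptor),
         src_layer = .layer_codes[[row$src]],
         tgt_layer = .layer_codes[[row$tgt]],
         receptor = .receptor_codes[[row$receptor]],
         g = row$g, depress = as.integer(row$depress), U = U,
         src = as.integer(conn$src - 1L), tgt = as.integer(conn$tgt - 1L))
  })
  structure(list(sizes = sizes, projections = plist, mapping = mapping),
            class = "tc_network")
}

#' @export
print.tc_network <- function(x, ...) {
  cat("Thalamocortical network:",
      paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = ", "),
      "\n")
  for (p in x$projections)
    cat(sprintf("  %-18s g=%.4f uS, %d connections\n", p$name, p$g,
                length(p$src)))
  invisible(x)
}

#' Miniature-EPSP drive parameters
#'
#' Poisson miniature EPSPs delivered to the AMPA receptors of PY and IN
#' dendrites while the network is in a Down state.  The drive re-arms
#' 100 ms after a slow-oscillation cycle terminates (50 ms of network-wide
#' PY silence) and is removed when the next cycle initiates (online SO
#' detection).  Rates are per cell; conductances per mini event.
#'
#' @param rate_py,rate_in event rate per target cell (Hz).
#' @param g_py,g_in mini conductance scale (uS).
#' @export
mini_drive <- function(rate_py = 6, rate_in = 6, g_py = 0.03,
                       g_in = 0.006) {
  stopifnot(rate_py >= 0, rate_in >= 0)
  list(rate_py = rate_py, rate_in = rate_in, g_py = g_py, g_in = g_in)
}
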