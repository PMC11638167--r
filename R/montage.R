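# ---- montage: electrode geometry and the distance prior ---------------------

#' Construct a montage layout
#'
#' A montage layout is the canonical node order of the electrode graph:
#' electrode labels plus 3-D head coordinates on a consistent length scale.
#' All graph matrices in the package (prior `E`, learned `P`) index nodes in
#' montage order.
#'
#' @param names Character vector of unique electrode labels (upper-cased).
#' @param coords Numeric matrix, one row per electrode, 3 columns (x right,
#'   y front, z up), any consistent unit.
#' @return An object of class `montage_layout` with elements `names` and
#'   `coords`.
#' @export
montage_layout <- function(names, coords) {
  names <- toupper(as.character(names))
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (anyDuplicated(names)) {
    stop("duplicate electrode labels: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  if (nrow(coords) != length(names)) {
    stop("coords must have one row per electrode (", length(names),
         "), got ", nrow(coords))
  }
  if (ncol(coords) != 3) stop("coords must have 3 columns (x, y, z)")
  if (!all(is.finite(coords))) stop("non-finite electrode coordinates")
  rownames(coords) <- names
  structure(list(names = names, coords = coords), class = "montage_layout")
}

#' @export
print.montage_layout <- function(x, ...) {
  cat("<montage_layout> ", length(x$names), " electrodes: ",
      paste(utils::head(x$names, 6), collapse = ", "),
      if (length(x$names) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Number of electrodes in a layout
#' @param layout A `montage_layout`.
#' @return Integer electrode count.
#' @export
n_channels <- function(layout) length(layout$names)

#' Load the built-in 64-channel 10-10 montage
#'
#' Returns the packaged 64-electrode extended international 10-10 layout
#' (the channel set used by PhysioNet-style 64-channel recordings), with
#' idealized unit-sphere scalp coordinates. Positions are derived from the
#' standard arc construction of the extended system: the head is a unit
#' sphere with the vertex (CZ) on top, the 10-10 circumference circle lies
#' at 72 degrees of inclination (through FPZ, T7, OZ, T8), midline
#' electrodes sit at 18-degree steps along the nasion-inion arc, and
#' interior row electrodes are spherical interpolations between the row's
#' midline and circumference members.
#'
#' Only relative distances matter downstream (the prior adjacency is scale
#' normalized), so the arbitrary unit-sphere radius is immaterial.
#'
#' @param n_channels Electrode count; only 64 has a built-in table. Custom
#'   layouts can be read with [read_montage_tsv()].
#' @return A [montage_layout()].
#' @export
load_builtin_montage <- function(n_channels = 64) {
  if (!identical(as.integer(n_channels), 64L)) {
    stop("no built-in montage with ", n_channels,
         " channels; only the 64-channel 10-10 layout is packaged ",
         "(use read_montage_tsv() for custom layouts)")
  }
  path <- system.file("extdata", "montage_1010_64.tsv", package = "dganet",
                      mustWork = TRUE)
  read_montage_tsv(path)
}

#' Read a montage from a TSV file
#'
#' Expects a header line `name<TAB>x<TAB>y<TAB>z` followed by one row per
#' electrode. This is the same dialect the packaged montage table uses, and
#' the format accepted by the command-line interface for custom layouts.
#'
#' @param path Path to the TSV file.
#' @return A [montage_layout()].
#' @export
read_montage_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(tab))) {
    stop("montage TSV must have columns name, x, y, z")
  }
  montage_layout(tab$name, as.matrix(tab[, c("x", "y", "z")]))
}

# Idealized spherical 10-10 coordinate generator (source of the packaged
# table; kept so the geometry is reproducible from code alone).
# Inclination alpha: degrees from the vertex; azimuth theta: degrees from
# the nasion direction, positive toward the left ear.
spherical_1010_coords <- function() {
  deg <- pi / 180
  pt <- function(alpha, theta) {
    a <- alpha * deg; t <- theta * deg
    c(x = -sin(a) * sin(t), y = sin(a) * cos(t), z = cos(a))
  }
  # great-circle interpolation from u toward v by fraction f
  slerp <- function(u, v, f) {
    om <- acos(max(-1, min(1, sum(u * v))))
    if (om < 1e-12) return(u)
    (sin((1 - f) * om) * u + sin(f * om) * v) / sin(om)
  }
  P <- list()
  # circumference circle (alpha = 72) at 18-degree azimuth steps
  circ <- c(FPZ = 0, FP1 = 18, AF7 = 36, F7 = 54, FT7 = 72, T7 = 90,
            TP7 = 108, P7 = 126, PO7 = 144, O1 = 162, OZ = 180,
            FP2 = -18, AF8 = -36, F8 = -54, FT8 = -72, T8 = -90,
            TP8 = -108, P8 = -126, PO8 = -144, O2 = -162)
  for (nm in names(circ)) P[[nm]] <- pt(72, circ[[nm]])
  # midline chain at 18-degree inclination steps
  mid <- list(AFZ = c(54, 0), FZ = c(36, 0), FCZ = c(18, 0), CZ = c(0, 0),
              CPZ = c(18, 180), PZ = c(36, 180), POZ = c(54, 180),
              IZ = c(90, 180))
  for (nm in names(mid)) P[[nm]] <- pt(mid[[nm]][1], mid[[nm]][2])
  # sub-circumference temporal electrodes at preauricular level
  P$T9 <- pt(90, 90); P$T10 <- pt(90, -90)
  # interior row electrodes: interpolate midline -> circumference endpoint
  rows <- list(
    AF = list(mid = "AFZ", endL = "AF7", endR = "AF8",
              L = c(AF3 = 0.5), R = c(AF4 = 0.5)),
    F  = list(mid = "FZ",  endL = "F7",  endR = "F8",
              L = c(F1 = 0.25, F3 = 0.5, F5 = 0.75),
              R = c(F2 = 0.25, F4 = 0.5, F6 = 0.75)),
    FC = list(mid = "FCZ", endL = "FT7", endR = "FT8",
              L = c(FC1 = 0.25, FC3 = 0.5, FC5 = 0.75),
              R = c(FC2 = 0.25, FC4 = 0.5, FC6 = 0.75)),
    C  = list(mid = "CZ",  endL = "T7",  endR = "T8",
              L = c(C1 = 0.25, C3 = 0.5, C5 = 0.75),
              R = c(C2 = 0.25, C4 = 0.5, C6 = 0.75)),
    CP = list(mid = "CPZ", endL = "TP7", endR = "TP8",
              L = c(CP1 = 0.25, CP3 = 0.5, CP5 = 0.75),
              R = c(CP2 = 0.25, CP4 = 0.5, CP6 = 0.75)),
    P  = list(mid = "PZ",  endL = "P7",  endR = "P8",
              L = c(P1 = 0.25, P3 = 0.5, P5 = 0.75),
              R = c(P2 = 0.25, P4 = 0.5, P6 = 0.75)),
    PO = list(mid = "POZ", endL = "PO7", endR = "PO8",
              L = c(PO3 = 0.5), R = c(PO4 = 0.5))
  )
  for (rw in rows) {
    for (nm in names(rw$L)) P[[nm]] <- slerp(P[[rw$mid]], P[[rw$endL]], rw$L[[nm]])
    for (nm in names(rw$R)) P[[nm]] <- slerp(P[[rw$mid]], P[[rw$endR]], rw$R[[nm]])
  }
  # canonical PhysioNet channel order = packaged montage order
  order64 <- c("FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6",
               "C5", "C3", "C1", "CZ", "C2", "C4", "C6",
               "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6",
               "FP1", "FPZ", "FP2",
               "AF7", "AF3", "AFZ", "AF4", "AF8",
               "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8",
               "FT7", "FT8", "T7", "T8", "T9", "T10", "TP7", "TP8",
               "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
               "PO7", "PO3", "POZ", "PO4", "PO8",
               "O1", "OZ", "O2", "IZ")
  coords <- t(vapply(order64, function(nm) P[[nm]], numeric(3)))
  montage_layout(order64, coords)
}

#' Pairwise electrode distances
#' @param layout A [montage_layout()].
#' @return C x C symmetric matrix of Euclidean distances.
#' @export
montage_distances <- function(layout) {
  D <- as.matrix(stats::dist(layout$coords))
  dimnames(D) <- list(layout$names, layout$names)
  D
}

#' Build the inverse-distance prior adjacency
#'
#' The electrode graph is seeded from geometry alone: the prior edge weight
#' between electrodes u and v is the reciprocal of their Euclidean distance,
#' so nearby electrodes start strongly connected. The diagonal is zero
#' (self-influence is handled by explicit self-loops in the attention
#' layers), and the matrix is rescaled so its largest off-diagonal entry is
#' 1, which makes downstream exponentiated products scale-stable; only
#' relative distances carry information.
#'
#' @param layout A [montage_layout()].
#' @return C x C matrix of class `prior_adjacency`: symmetric, zero
#'   diagonal, all off-diagonal entries in (0, 1] with max exactly 1.
#' @export
build_prior_adjacency <- function(layout) {
  D <- montage_distances(layout)
  off <- upper.tri(D)
  if (any(D[off] == 0)) {
    bad <- which(D == 0 & upper.tri(D), arr.ind = TRUE)[1, ]
    stop("electrodes at identical coordinates: ",
         layout$names[bad[1]], " and ", layout$names[bad[2]])
  }
  E <- 1 / D
  diag(E) <- 0
  E <- E / max(E)
  dimnames(E) <- list(layout$names, layout$names)
  class(E) <- c("prior_adjacency", class(E))
  E
}
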