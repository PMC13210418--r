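#' Digital phantoms for spectral radiography
#'
#' Phantoms are represented as paired per-pixel path-length ("thickness")
#' maps of the two basis materials, aluminum and PMMA, in mm, together with
#' a registry of circular inserts. Coordinates use pixel centers with x
#' rightward (columns) and y downward (rows), both starting at 0 at the top
#' left corner of the field; the center of pixel (row i, col j), 1-based, is
#' at ((j - 0.5) * pitch, (i - 0.5) * pitch) mm. A pixel belongs to a disk
#' iff its center lies at distance <= radius from the disk center.
#'
#' @name phantoms
NULL

new_thickness_maps <- function(al, pmma, pitch) {
  stopifnot(identical(dim(al), dim(pmma)), all(al >= 0), all(pmma >= 0),
            pitch > 0)
  structure(list(al = al, pmma = pmma, pitch = pitch),
            class = "thickness_maps")
}

#' Construct an insert registry row
#'
#' @param center_x_mm,center_y_mm disk center in mm.
#' @param radius_mm disk radius in mm (> 0).
#' @param material `"al"` or `"pmma"`.
#' @param delta_mm additional thickness over the background in mm (>= 0).
#' @return one-row data frame.
#' @export
insert_spec <- function(center_x_mm, center_y_mm, radius_mm, material,
                        delta_mm) {
  stopifnot(radius_mm > 0, delta_mm >= 0, material %in% c("al", "pmma"))
  data.frame(center_x_mm = center_x_mm, center_y_mm = center_y_mm,
             radius_mm = radius_mm, material = material, delta_mm = delta_mm,
             stringsAsFactors = FALSE)
}

disk_mask <- function(dim_px, pitch, cx, cy, r) {
  x <- (seq_len(dim_px[2]) - 0.5) * pitch
  y <- (seq_len(dim_px[1]) - 0.5) * pitch
  outer((y - cy)^2, (x - cx)^2, `+`) <= r^2
}

assert_no_overlap <- function(inserts) {
  n <- nrow(inserts)
  if (n < 2) return(invisible(TRUE))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d <- sqrt((inserts$center_x_mm[i] - inserts$center_x_mm[j])^2 +
                (inserts$center_y_mm[i] - inserts$center_y_mm[j])^2)
    # interiors must be disjoint; tangent disks are allowed
    if (d < inserts$radius_mm[i] + inserts$radius_mm[j] - 1e-9)
      stop("inserts ", i, " and ", j, " overlap")
  }
  invisible(TRUE)
}

build_bundle <- function(size_mm, pitch, bg_al, bg_pmma, inserts, kind,
                         signal_insert = NA_integer_) {
  if (pitch <= 0) stop("pitch must be positive")
  n <- size_mm / pitch
  if (abs(n - round(n)) > 1e-9) stop("pitch must divide ", size_mm, " mm evenly")
  n <- round(n)
  assert_no_overlap(inserts)
  al <- matrix(bg_al, n, n)
  pmma <- matrix(bg_pmma, n, n)
  for (i in seq_len(nrow(inserts))) {
    m <- disk_mask(c(n, n), pitch, inserts$center_x_mm[i],
                   inserts$center_y_mm[i], inserts$radius_mm[i])
    if (inserts$material[i] == "al") al[m] <- al[m] + inserts$delta_mm[i]
    else pmma[m] <- pmma[m] + inserts$delta_mm[i]
  }
  structure(
    list(maps = new_thickness_maps(al, pmma, pitch), inserts = inserts,
         kind = kind, signal_insert = signal_insert,
         background = c(al = bg_al, pmma = bg_pmma), size_mm = size_mm),
    class = "phantom_bundle")
}

#' Quantitative-accuracy phantom
#'
#' A 150 x 150 mm LucAl-style slab (uniform background 4.1 mm Al + 83 mm
#' PMMA) with ten circular inserts of radius 12.5 mm: five Al inserts adding
#' 0.5, 1.0, 1.5, 2.0, 2.5 mm (top row, y = 50 mm, x = 25..125 mm) and five
#' PMMA inserts adding 2, 4, 6, 8, 10 mm (bottom row, y = 100 mm). Each
#' insert raises exactly one material map inside its disk.
#'
#' @param pitch micro-pixel pitch in mm (must divide 150 evenly).
#' @return a `phantom_bundle` with fields `maps` (`thickness_maps`),
#'   `inserts` (registry data frame), `kind`, `background`.
#' @export
build_quant_phantom <- function(pitch = 0.1) {
  xs <- c(25, 50, 75, 100, 125)
  inserts <- rbind(
    do.call(rbind, Map(insert_spec, xs, 50, 12.5, "al",
                       c(0.5, 1.0, 1.5, 2.0, 2.5))),
    do.call(rbind, Map(insert_spec, xs, 100, 12.5, "pmma",
                       c(2, 4, 6, 8, 10))))
  build_bundle(150, pitch, 4.1, 83.0, inserts, "quant")
}

#' Low-contrast-detectability phantoms
#'
#' A 100 x 100 mm slab on the same LucAl background (4.1 mm Al + 83 mm
#' PMMA) with disk inserts of radius 2 mm. For the aluminum task
#' (`"al_lcd"`) the signal disk adds 0.1 mm Al and four non-target disks add
#' 10 mm PMMA; for the PMMA task (`"pmma_lcd"`) the signal disk adds 0.1 mm
#' PMMA and the non-targets add 2.5 mm Al. The signal disk sits at
#' (25, 50) mm in the left half, which otherwise stays uniform for
#' false-positive searching; the non-targets occupy a 2 x 2 grid in the
#' right half.
#'
#' @param task `"al_lcd"` or `"pmma_lcd"`.
#' @param pitch micro-pixel pitch in mm (must divide 100 evenly).
#' @return a `phantom_bundle`; `signal_insert` indexes the removable target
#'   disk in the registry.
#' @export
build_lcd_phantom <- function(task = c("al_lcd", "pmma_lcd"), pitch = 0.1) {
  task <- match.arg(task)
  sig_mat <- if (task == "al_lcd") "al" else "pmma"
  nt_mat <- if (task == "al_lcd") "pmma" else "al"
  nt_delta <- if (task == "al_lcd") 10.0 else 2.5
  inserts <- rbind(
    insert_spec(25, 50, 2, sig_mat, 0.1),
    do.call(rbind, Map(insert_spec, c(65, 85, 65, 85), c(35, 35, 65, 65),
                       2, nt_mat, nt_delta)))
  build_bundle(100, pitch, 4.1, 83.0, inserts, task, signal_insert = 1L)
}

#' Remove an insert from a phantom
#'
#' Subtracts the indexed insert's thickness delta inside its disk, leaving
#' every other pixel bit-identical; re-adding the insert restores the
#' original maps exactly.
#'
#' @param bundle a `phantom_bundle`.
#' @param index insert registry row to remove.
#' @return a `phantom_bundle` whose registry no longer carries the insert.
#' @export
remove_insert <- function(bundle, index) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  if (index < 1 || index > nrow(bundle$inserts)) stop("index out of range")
  ins <- bundle$inserts[index, ]
  m <- disk_mask(dim(bundle$maps$al), bundle$maps$pitch, ins$center_x_mm,
                 ins$center_y_mm, ins$radius_mm)
  if (ins$material == "al") bundle$maps$al[m] <- bundle$maps$al[m] - ins$delta_mm
  else bundle$maps$pmma[m] <- bundle$maps$pmma[m] - ins$delta_mm
  bundle$inserts <- bundle$inserts[-index, ]
  if (!is.na(bundle$signal_insert)) {
    if (bundle$signal_insert == index) bundle$signal_insert <- NA_integer_
    else if (bundle$signal_insert > index)
      bundle$signal_insert <- bundle$signal_insert - 1L
  }
  bundle
}

#' Export an insert registry as CSV
#' @param bundle a `phantom_bundle`.
#' @param path output file.
#' @export
export_insert_registry <- function(bundle, path) {
  utils::write.csv(bundle$inserts, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf("<phantom_bundle> kind = %s, %d x %d px at %.3g mm, %d inserts\n",
              x$kind, nrow(x$maps$al), ncol(x$maps$al), x$maps$pitch,
              nrow(x$inserts)))
  cat(sprintf("  background: %.1f mm Al + %.1f mm PMMA\n",
              x$background["al"], x$background["pmma"]))
  invisible(x)
}

#' @export
print.thickness_maps <- function(x, ...) {
  cat(sprintf("<thickness_maps> %d x %d px at %.3g mm/px\n",
              nrow(x$al), ncol(x$al), x$pitch))
  cat(sprintf("  al in [%.3g, %.3g] mm, pmma in [%.3g, %.3g] mm\n",
              min(x$al), max(x$al), min(x$pmma), max(x$pmma)))
  invisible(x)
}
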