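#' Build a virtual-color scheme over reference lengths
#'
#' Virtual colors are overlapping, fixed-extent bins laid over each
#' reference, treated as distinct colors during pseudoalignment so that a
#' read's k-mer intersection is positionally local. The bin stride is
#' `lvcol` bases and each bin overlaps the bin on its left by `ov_length`
#' bases: the leftmost bin of a reference covers `lvcol` bases, interior
#' bins `ov_length + lvcol`, and the rightmost bin `ov_length + rl` bases
#' where `(B-1) * lvcol + rl = L`. A reference of length `L` carries
#' `B = ceiling(L / lvcol)` bins; bins never span two references. Virtual
#' color ids are global and 0-based: reference `i` owns ids
#' `CB[i] .. CB[i] + B[i] - 1` where `CB` is the cumulative bin count of
#' the preceding references.
#'
#' The scheme is a pure function of the reference lengths and the two
#' parameters; it is computed on the fly and never serialized with the
#' index.
#'
#' @param lengths reference lengths in bases, or a [reference_set()] /
#'   [build_index()] object to take them from.
#' @param lvcol bin stride in bases (>= 1). The default 1000 is the setting
#'   with the best observed mapping accuracy. Passing a value >= the longest
#'   reference degenerates to one bin per reference (classic whole-sequence
#'   colors).
#' @param ov_length overlap extent in bases (0 <= ov_length <= lvcol). Must
#'   be at least the read length for boundary-spanning reads not to be
#'   lost; a warning is emitted when `read_length` is supplied and exceeds
#'   it.
#' @param read_length optional intended read length, used only for the
#'   warning above.
#' @return an object of class `vcolor_scheme` with fields `lvcol`,
#'   `ov_length`, `lengths`, `B`, `CB`, `total_vcols`.
#' @examples
#' sc <- build_scheme(c(2500, 1800), lvcol = 1000, ov_length = 100)
#' sc$B          # 3 2
#' sc$CB         # 0 3
#' sc$total_vcols
#' @export
build_scheme <- function(lengths, lvcol = 1000L, ov_length = 150L,
                         read_length = NULL) {
  if (inherits(lengths, "reference_set")) lengths <- lengths$L
  if (inherits(lengths, "dbg_index")) lengths <- lengths$ref_len
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0L || any(is.na(lengths)) || any(lengths < 1))
    stop("all reference lengths must be >= 1")
  lvcol <- as.numeric(lvcol)
  if (length(lvcol) != 1L || is.na(lvcol) || lvcol < 1)
    stop("lvcol must be a positive integer")
  ov_length <- as.numeric(ov_length)
  if (length(ov_length) != 1L || is.na(ov_length) || ov_length < 0)
    stop("ov_length must be non-negative")
  if (ov_length > lvcol)
    stop("ov_length must not exceed lvcol: bins only overlap their left ",
         "neighbor, so a k-mer carries at most two virtual colors")
  if (!is.null(read_length) && ov_length < read_length)
    warning("ov_length (", ov_length, ") is smaller than the read length (",
            read_length, "); reads spanning bin boundaries may be lost")
  B <- as.integer(ceiling(lengths / lvcol))
  CB <- as.integer(cumsum(c(0L, B[-length(B)])))
  structure(list(lvcol = as.integer(lvcol), ov_length = as.integer(ov_length),
                 lengths = as.integer(lengths), B = B, CB = CB,
                 total_vcols = sum(B)),
            class = "vcolor_scheme")
}

#' @export
print.vcolor_scheme <- function(x, ...) {
  cat(sprintf("vcolor_scheme: lvcol=%d, ov_length=%d, %d reference(s), %d virtual colors\n",
              x$lvcol, x$ov_length, length(x$B), x$total_vcols))
  invisible(x)
}

#' Virtual color id(s) of a reference position
#'
#' A position `p` on reference `ref` always carries the base id
#' `V = CB[ref] + floor(p / lvcol)`; it additionally carries `V + 1` when
#' it lies in the overlap region of the next bin
#' (`p %% lvcol >= lvcol - ov_length`) and that bin exists on the same
#' reference -- the extra id is suppressed at the last bin so no bin ever
#' crosses a reference boundary.
#'
#' @param scheme a [build_scheme()] result.
#' @param ref 0-based reference id.
#' @param pos 0-based position (k-mer start) on the reference forward
#'   strand.
#' @return integer vector of one or two 0-based virtual color ids.
#' @examples
#' sc <- build_scheme(3000, lvcol = 1000, ov_length = 100)
#' assign_vcolors(sc, 0, 1500)   # 1
#' assign_vcolors(sc, 0, 950)    # 0 1
#' assign_vcolors(sc, 0, 2950)   # 2 (no bin beyond the last)
#' @export
assign_vcolors <- function(scheme, ref, pos) {
  stopifnot(inherits(scheme, "vcolor_scheme"))
  ref <- as.integer(ref); pos <- as.integer(pos)
  if (length(ref) != 1L || is.na(ref) || ref < 0L || ref >= length(scheme$B))
    stop("ref id out of range")
  if (length(pos) != 1L || is.na(pos) || pos < 0L || pos >= scheme$lengths[ref + 1L])
    stop("position out of range for reference ", ref)
  b <- pos %/% scheme$lvcol
  v <- scheme$CB[ref + 1L] + b
  if (pos %% scheme$lvcol >= scheme$lvcol - scheme$ov_length &&
      b + 1L < scheme$B[ref + 1L]) c(v, v + 1L) else v
}

#' Reference interval covered by a virtual color
#'
#' Inverse view of [assign_vcolors()]: bin `b` of reference `Ri` covers the
#' half-open interval `[max(0, b*lvcol - ov_length), min(L, (b+1)*lvcol))`.
#' For every position `p`, `vid` is in `assign_vcolors(p)` exactly when `p`
#' lies in `vcolor_interval(vid)`.
#'
#' @param scheme a [build_scheme()] result.
#' @param vid 0-based virtual color id.
#' @return named integer vector `c(ref, start, end)` (end exclusive).
#' @export
vcolor_interval <- function(scheme, vid) {
  stopifnot(inherits(scheme, "vcolor_scheme"))
  vid <- as.integer(vid)
  if (length(vid) != 1L || is.na(vid) || vid < 0L || vid >= scheme$total_vcols)
    stop("virtual color id out of range")
  ref <- findInterval(vid, scheme$CB) - 1L
  b <- vid - scheme$CB[ref + 1L]
  L <- scheme$lengths[ref + 1L]
  c(ref = ref,
    start = max(0L, b * scheme$lvcol - scheme$ov_length),
    end = min(L, (b + 1L) * scheme$lvcol))
}
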