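#' Time bins for disparity and rate analyses
#'
#' Two binning schemes: `"equal"` builds consecutive bins of fixed width
#' (default 10 my) starting at `oldest` and extending until `youngest` is
#' covered; with the defaults (251.3 to 93.9 Ma, 10 my) this yields 16 bins
#' whose boundaries align with the Triassic-Jurassic boundary at 201.3 Ma.
#' `"epoch"` uses the eight Mesozoic epoch-level bins (Early/Middle/Late
#' Triassic, Early/Middle/Late Jurassic, Early/Late Cretaceous) clipped to
#' `[oldest, youngest]`.
#'
#' @param scheme `"equal"` or `"epoch"`.
#' @param oldest,youngest bin span in Ma (oldest > youngest).
#' @param width bin width in my for the equal scheme.
#' @return object of class `time_bins`: data frame with columns `label`,
#'   `old`, `young` (ages in Ma, strictly decreasing), plus attribute
#'   `scheme`.
#' @examples
#' make_bins("equal")        # 16 x 10-my bins
#' make_bins("epoch")        # 8 epoch bins
#' @export
make_bins <- function(scheme = c("equal", "epoch"), oldest = 251.3,
                      youngest = 93.9, width = 10) {
  scheme <- match.arg(scheme)
  if (oldest <= youngest) stop("`oldest` must exceed `youngest`")
  if (scheme == "equal") {
    if (width <= 0) stop("`width` must be positive")
    n <- ceiling((oldest - youngest) / width)
    old <- oldest - width * (seq_len(n) - 1)
    young <- old - width
    label <- sprintf("%.1f-%.1f", old, young)
  } else {
    ep <- .mesozoic_epochs()
    old <- pmin(ep$old, oldest)
    young <- pmax(ep$young, youngest)
    keep <- old > young
    old <- old[keep]; young <- young[keep]; label <- ep$label[keep]
  }
  bins <- data.frame(label = label, old = old, young = young,
                     stringsAsFactors = FALSE)
  structure(bins, scheme = scheme, class = c("time_bins", "data.frame"))
}

## ICS epoch boundaries (Ma) for the Mesozoic
.mesozoic_epochs <- function() {
  data.frame(
    label = c("Early Triassic", "Middle Triassic", "Late Triassic",
              "Early Jurassic", "Middle Jurassic", "Late Jurassic",
              "Early Cretaceous", "Late Cretaceous"),
    old = c(251.902, 247.2, 237.0, 201.3, 174.1, 163.5, 145.0, 100.5),
    young = c(247.2, 237.0, 201.3, 174.1, 163.5, 145.0, 100.5, 66.0),
    stringsAsFactors = FALSE
  )
}

#' @export
print.time_bins <- function(x, ...) {
  cat(sprintf("%s time bins (%d): %s to %s Ma\n", attr(x, "scheme"),
              nrow(x), format(max(x$old)), format(min(x$young))))
  print.data.frame(x)
  invisible(x)
}

#' Assign taxa to time bins from stratigraphic ranges
#'
#' A taxon belongs to a bin iff its `[LAD, FAD]` range overlaps the bin
#' interval with positive measure; a point range (`FAD == LAD`) lying
#' strictly inside a bin belongs to that bin, and a point range lying on a
#' bin boundary is assigned to the younger bin only. Taxa may occupy several
#' bins. Taxa whose range falls entirely outside every bin are excluded with
#' a warning.
#'
#' @param ranges data frame with columns `taxon`, `fad`, `lad` (ages in Ma,
#'   `fad >= lad`).
#' @param bins a [make_bins()] result.
#' @return named list (one element per bin label) of character vectors of
#'   taxon names.
#' @export
assign_taxa_to_bins <- function(ranges, bins) {
  stopifnot(inherits(bins, "time_bins"))
  ranges <- .check_ranges(ranges)
  out <- lapply(seq_len(nrow(bins)), function(i) {
    old <- bins$old[i]; young <- bins$young[i]
    hit <- mapply(function(fad, lad) {
      if (fad > lad) {
        min(fad, old) - max(lad, young) > 0
      } else {
        # point range: (young, old], so boundaries go to the younger bin
        fad > young && fad <= old
      }
    }, ranges$fad, ranges$lad)
    ranges$taxon[hit]
  })
  names(out) <- bins$label
  orphan <- setdiff(ranges$taxon, unlist(out))
  if (length(orphan))
    warning("taxa outside all bins excluded: ",
            paste(orphan, collapse = ", "))
  out
}

.check_ranges <- function(ranges) {
  ranges <- as.data.frame(ranges)
  need <- c("taxon", "fad", "lad")
  if (!all(need %in% names(ranges)))
    stop("ranges must have columns taxon, fad, lad")
  if (any(ranges$fad < ranges$lad))
    stop("FAD must be >= LAD for every taxon")
  if (any(ranges$lad <= 0)) stop("ages must be positive (Ma)")
  ranges
}

#' Read a stratigraphic range table
#'
#' CSV with columns `taxon`, `fad`, `lad` (first/last appearance dates, Ma).
#'
#' @param path CSV file path.
#' @return validated data frame.
#' @export
read_strat_ranges <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  .check_ranges(df)
}
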