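#' Construct a geological time-bin scheme
#'
#' A bin scheme is an ordered set of contiguous geological intervals, oldest
#' first, with ages in Ma before present. Each bin is the closed interval
#' \[`top_ma`, `base_ma`\]; `duration_myr` is `base_ma - top_ma`.
#'
#' @param name Character vector of bin names.
#' @param base_ma Numeric vector of older boundaries (Ma).
#' @param top_ma Numeric vector of younger boundaries (Ma).
#' @param scheme Label for the scheme (`"stage"`, `"tenmyr"` or `"custom"`).
#' @return A `bin_scheme` data frame (columns `name`, `base_ma`, `top_ma`,
#'   `midpoint_ma`, `duration_myr`), ordered oldest first.
#' @examples
#' bin_scheme(c("older", "younger"), c(160, 150), c(150, 140))
#' @export
bin_scheme <- function(name, base_ma, top_ma, scheme = "custom") {
  if (length(name) == 0L) {
    stop("configuration error: bin scheme is empty", call. = FALSE)
  }
  if (length(name) != length(base_ma) || length(base_ma) != length(top_ma)) {
    stop("name, base_ma and top_ma must have equal length", call. = FALSE)
  }
  base_ma <- as.numeric(base_ma)
  top_ma <- as.numeric(top_ma)
  if (anyNA(base_ma) || anyNA(top_ma) ||
      any(!is.finite(base_ma)) || any(!is.finite(top_ma))) {
    stop("bin boundaries must be finite numbers", call. = FALSE)
  }
  if (any(base_ma <= top_ma)) {
    stop("each bin must have base_ma > top_ma", call. = FALSE)
  }
  o <- order(base_ma, decreasing = TRUE)
  name <- as.character(name)[o]
  base_ma <- base_ma[o]
  top_ma <- top_ma[o]
  n <- length(name)
  if (anyDuplicated(name)) {
    stop("bin names must be unique", call. = FALSE)
  }
  if (n > 1L && any(abs(top_ma[-n] - base_ma[-1L]) > 1e-6)) {
    stop("bins must be contiguous: each bin's top_ma must equal the next bin's base_ma",
         call. = FALSE)
  }
  out <- data.frame(
    name = name,
    base_ma = base_ma,
    top_ma = top_ma,
    midpoint_ma = (base_ma + top_ma) / 2,
    duration_myr = base_ma - top_ma,
    stringsAsFactors = FALSE
  )
  attr(out, "scheme") <- scheme
  class(out) <- c("bin_scheme", "data.frame")
  out
}

#' Jurassic--Cretaceous stage-level bin scheme
#'
#' Standard European stages of the Jurassic and Cretaceous with Gradstein
#' et al. (2012) boundary ages, Hettangian (201.3 Ma) through Maastrichtian
#' (66.0 Ma).
#'
#' @return A `bin_scheme` with 23 stage bins.
#' @export
jk_stage_bins <- function() {
  bin_scheme(
    name = c("Hettangian", "Sinemurian", "Pliensbachian", "Toarcian",
             "Aalenian", "Bajocian", "Bathonian", "Callovian", "Oxfordian",
             "Kimmeridgian", "Tithonian", "Berriasian", "Valanginian",
             "Hauterivian", "Barremian", "Aptian", "Albian", "Cenomanian",
             "Turonian", "Coniacian", "Santonian", "Campanian",
             "Maastrichtian"),
    base_ma = c(201.3, 199.3, 190.8, 182.7, 174.1, 170.3, 168.3, 166.1,
                163.5, 157.3, 152.1, 145.0, 139.8, 132.9, 129.4, 125.0,
                113.0, 100.5, 93.9, 89.8, 86.3, 83.6, 72.1),
    top_ma = c(199.3, 190.8, 182.7, 174.1, 170.3, 168.3, 166.1, 163.5,
               157.3, 152.1, 145.0, 139.8, 132.9, 129.4, 125.0, 113.0,
               100.5, 93.9, 89.8, 86.3, 83.6, 72.1, 66.0),
    scheme = "stage"
  )
}

#' Approximately equal 10-Myr Jurassic--Cretaceous bins
#'
#' Uniform division of the Jurassic--Cretaceous (201.3--66.0 Ma) into 14
#' bins of ~9.66 Myr each, used where stage bins of uneven length
#' (2--13 Myr) would distort per-bin sample pools.
#'
#' @return A `bin_scheme` with 14 bins labelled `tenmyr01` (oldest) onward.
#' @export
jk_tenmyr_bins <- function() {
  make_uniform_bins(201.3, 66.0, n_bins = 14L, prefix = "tenmyr",
                    scheme = "tenmyr")
}

#' Uniform bin scheme over an age span
#'
#' @param base_ma Older end of the span (Ma).
#' @param top_ma Younger end of the span (Ma).
#' @param n_bins Number of equal-duration bins.
#' @param prefix Name prefix; bins are numbered oldest first.
#' @param scheme Scheme label.
#' @return A `bin_scheme`.
#' @export
make_uniform_bins <- function(base_ma, top_ma, n_bins, prefix = "bin",
                              scheme = "custom") {
  stopifnot(base_ma > top_ma, n_bins >= 1L)
  edges <- seq(base_ma, top_ma, length.out = n_bins + 1L)
  bin_scheme(
    name = sprintf("%s%02d", prefix, seq_len(n_bins)),
    base_ma = edges[-(n_bins + 1L)],
    top_ma = edges[-1L],
    scheme = scheme
  )
}

#' Read a bin scheme from CSV
#'
#' Expects columns `name`, `base_ma`, `top_ma`.
#'
#' @param path CSV file path.
#' @param scheme Scheme label to attach.
#' @return A `bin_scheme`.
#' @export
read_bin_scheme <- function(path, scheme = "custom") {
  if (!file.exists(path)) {
    stop("configuration error: bin scheme file not found: ", path,
         call. = FALSE)
  }
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "base_ma", "top_ma")
  if (!all(need %in% names(x))) {
    stop("format error: bin scheme CSV must have columns name, base_ma, top_ma",
         call. = FALSE)
  }
  bin_scheme(x$name, x$base_ma, x$top_ma, scheme = scheme)
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("<bin_scheme '%s': %d bins, %.1f-%.1f Ma>\n",
              attr(x, "scheme") %||% "custom", nrow(x),
              max(x$base_ma), min(x$top_ma)))
  print(as.data.frame(x), ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
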