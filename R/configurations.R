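#' Axial extent of a syrinx segment
#'
#' The segmented syrinx region is divided into twenty-seven 10 mm segments
#' and one 15 mm segment at the caudal end, so segment `i` spans
#' `[(i-1)*10, i*10]` mm for `i <= 27` and `[270, 285]` mm for `i = 28`.
#'
#' @param i Segment index (vectorized), `1..28`.
#' @param segment_lengths_mm Segment lengths; default 27 x 10 mm + 15 mm.
#' @return A tibble with columns `segment`, `x_start_mm`, `x_end_mm`.
#' @export
#' @examples
#' segment_extent(8)   # 70 -- 80 mm
#' segment_extent(28)  # 270 -- 285 mm
segment_extent <- function(i, segment_lengths_mm = c(rep(10, 27), 15)) {
  n <- length(segment_lengths_mm)
  if (any(i < 1 | i > n | i != round(i))) {
    stop("segment index must be an integer in 1..", n, call. = FALSE)
  }
  ends <- cumsum(segment_lengths_mm)
  starts <- ends - segment_lengths_mm
  tibble::tibble(segment = as.integer(i),
                 x_start_mm = starts[i], x_end_mm = ends[i])
}

#' Syrinx occupancy patterns
#'
#' A pattern records which of the 28 syrinx segments hold fluid, the rule
#' used for the syrinx radius (`"fixed_ratio"`: a constant fraction of the
#' cord radius, used for the single small syringes; `"mri_like"`: the
#' anatomy's maximum-radius profile, used for the expanding series), and a
#' canonical name: `"baseline"`, `"S<i>"`, or `"S1-<j>"`.
#'
#' @param occupancy Logical vector, one entry per segment.
#' @param radius_rule `"fixed_ratio"` or `"mri_like"` (ignored when no
#'   segment is occupied).
#' @param ratio Syrinx/cord radius ratio for `fixed_ratio` (default 0.70).
#' @param name Canonical configuration name; derived if omitted.
#' @return A list of class `syrinx_pattern`.
#' @export
syrinx_pattern <- function(occupancy,
                           radius_rule = c("fixed_ratio", "mri_like"),
                           ratio = 0.70, name = NULL) {
  radius_rule <- match.arg(radius_rule)
  occupancy <- as.logical(occupancy)
  if (any(is.na(occupancy))) stop("occupancy must be TRUE/FALSE", call. = FALSE)
  if (!(ratio > 0 && ratio < 1)) {
    stop("ratio must lie in (0, 1)", call. = FALSE)
  }
  if (is.null(name)) name <- pattern_name(occupancy)
  structure(list(occupancy = occupancy, radius_rule = radius_rule,
                 ratio = ratio, name = name),
            class = "syrinx_pattern")
}

pattern_name <- function(occupancy) {
  idx <- which(occupancy)
  if (length(idx) == 0) return("baseline")
  if (length(idx) == 1) return(paste0("S", idx))
  if (identical(idx, seq_len(length(idx)))) {
    return(paste0("S1-", max(idx)))
  }
  paste0("custom[", paste(idx, collapse = ","), "]")
}

#' Parse a canonical configuration name into its pattern
#'
#' Accepts `"baseline"`, `"S<i>"` (single small syrinx, fixed 70% radius
#' ratio) and `"S1-<j>"` (expanding syrinx, MRI-like radii).  Underscored
#' spellings such as `"S_8"` and `"S_1-8"` are also accepted.
#'
#' @param name Configuration name.
#' @param n_segments Number of syrinx segments (default 28).
#' @return A `syrinx_pattern`.
#' @export
parse_config_name <- function(name, n_segments = 28) {
  raw <- gsub("_", "", trimws(name))
  if (identical(tolower(raw), "baseline")) {
    return(syrinx_pattern(rep(FALSE, n_segments), name = "baseline"))
  }
  if (grepl("^S1-[0-9]+$", raw)) {
    j <- as.integer(sub("^S1-", "", raw))
    if (j < 1 || j > n_segments) stop("segment index out of range in ", name,
                                      call. = FALSE)
    return(syrinx_pattern(seq_len(n_segments) <= j, radius_rule = "mri_like",
                          name = paste0("S1-", j)))
  }
  if (grepl("^S[0-9]+$", raw)) {
    i <- as.integer(sub("^S", "", raw))
    if (i < 1 || i > n_segments) stop("segment index out of range in ", name,
                                      call. = FALSE)
    return(syrinx_pattern(seq_len(n_segments) == i, radius_rule = "fixed_ratio",
                          name = paste0("S", i)))
  }
  stop("unrecognized configuration name: ", name, call. = FALSE)
}

# Effective per-station syrinx radius for a pattern over an anatomy grid.
# Segment occupancy is half-open [start, end) on the station grid; the
# final station of the last occupied segment block is included when the
# block closes the syrinx region (x = 285 mm for segment 28).
effective_syrinx_radius <- function(anatomy, pattern) {
  params <- attr(anatomy, "params")
  ext <- segment_extent(seq_along(pattern$occupancy),
                        params$segment_lengths_mm)
  x <- anatomy$x_mm
  occupied <- rep(FALSE, length(x))
  region_end <- max(ext$x_end_mm)
  for (i in which(pattern$occupancy)) {
    lo <- ext$x_start_mm[i]
    hi <- ext$x_end_mm[i]
    occupied <- occupied | (x >= lo & x < hi) |
      (abs(hi - region_end) < 1e-9 & abs(x - hi) < 1e-9)
  }
  r <- rep(0, length(x))
  if (pattern$radius_rule == "fixed_ratio") {
    r[occupied] <- pattern$ratio * anatomy$r_cord_mm[occupied]
  } else {
    r[occupied] <- anatomy$r_syrinx_max_mm[occupied]
  }
  r
}

new_config <- function(anatomy, pattern) {
  cfg <- anatomy
  cfg$r_syrinx_mm <- effective_syrinx_radius(anatomy, pattern)
  attr(cfg, "pattern") <- pattern
  attr(cfg, "name") <- pattern$name
  class(cfg) <- c("slosh_config", setdiff(class(anatomy), "slosh_config"))
  cfg
}

#' Build model configurations
#'
#' `make_baseline()` is the syrinx-free reference; `make_single_syrinx()`
#' places one small syrinx in segment `i` with radius a fixed 70% of the
#' cord radius; `make_expanding_syrinx()` fills segments `1..j` with the
#' MRI-like radius profile, emulating a syrinx growing caudally from the
#' cranial end.
#'
#' @param anatomy A `slosh_anatomy` profile.
#' @param i,j Segment index, `1..28`.
#' @param ratio Syrinx/cord radius ratio for single syringes.
#' @return A `slosh_config`: the anatomy tibble with an `r_syrinx_mm`
#'   column (zero off-syrinx) and the pattern attached as attributes
#'   `pattern` and `name`.
#' @export
#' @examples
#' anat <- synthesize_anatomy()
#' s8 <- make_single_syrinx(anat, 8)
#' config_extent(s8)  # 70 80
make_single_syrinx <- function(anatomy, i, ratio = 0.70) {
  n <- length(attr(anatomy, "params")$segment_lengths_mm)
  if (length(i) != 1 || i < 1 || i > n || i != round(i)) {
    stop("segment index must be a single integer in 1..", n, call. = FALSE)
  }
  new_config(anatomy, syrinx_pattern(seq_len(n) == i,
                                     radius_rule = "fixed_ratio",
                                     ratio = ratio))
}

#' @rdname make_single_syrinx
#' @export
make_expanding_syrinx <- function(anatomy, j) {
  n <- length(attr(anatomy, "params")$segment_lengths_mm)
  if (length(j) != 1 || j < 1 || j > n || j != round(j)) {
    stop("segment index must be a single integer in 1..", n, call. = FALSE)
  }
  new_config(anatomy, syrinx_pattern(seq_len(n) <= j,
                                     radius_rule = "mri_like",
                                     name = paste0("S1-", j)))
}

#' @rdname make_single_syrinx
#' @export
make_baseline <- function(anatomy) {
  n <- length(attr(anatomy, "params")$segment_lengths_mm)
  new_config(anatomy, syrinx_pattern(rep(FALSE, n)))
}

#' Axial extent of a configuration's syrinx
#'
#' @param config A `slosh_config`.
#' @return `c(x_start_mm, x_end_mm)` of the occupied block, or `NULL` for
#'   the baseline.
#' @export
config_extent <- function(config) {
  pattern <- attr(config, "pattern")
  idx <- which(pattern$occupancy)
  if (!length(idx)) return(NULL)
  params <- attr(config, "params")
  ext <- segment_extent(idx, params$segment_lengths_mm)
  c(min(ext$x_start_mm), max(ext$x_end_mm))
}

#' Enumerate the full study suite
#'
#' Builds, in order, the baseline, the 28 single-syrinx configurations
#' `S1..S28`, and the 28 expanding configurations `S1-1..S1-28` — 57
#' configurations in total.
#'
#' @param anatomy A `slosh_anatomy` profile.
#' @return A named list of 57 `slosh_config` objects.
#' @export
enumerate_suite <- function(anatomy) {
  n <- length(attr(anatomy, "params")$segment_lengths_mm)
  configs <- c(
    list(make_baseline(anatomy)),
    purrr::map(seq_len(n), ~ make_single_syrinx(anatomy, .x)),
    purrr::map(seq_len(n), ~ make_expanding_syrinx(anatomy, .x))
  )
  names(configs) <- purrr::map_chr(configs, ~ attr(.x, "name"))
  configs
}

#' Suite manifest table
#'
#' @param anatomy A `slosh_anatomy` profile.
#' @return A tibble `name, kind, x_start_mm, x_end_mm, length_mm` with one
#'   row per configuration (extent columns `NA` for the baseline).
#' @export
suite_manifest <- function(anatomy) {
  configs <- enumerate_suite(anatomy)
  purrr::map_dfr(configs, function(cfg) {
    ext <- config_extent(cfg)
    pattern <- attr(cfg, "pattern")
    nm <- attr(cfg, "name")
    kind <- if (!any(pattern$occupancy)) {
      "baseline"
    } else if (grepl("^S1-", nm)) {
      "expanding"
    } else {
      "single"
    }
    tibble::tibble(
      name = attr(cfg, "name"), kind = kind,
      x_start_mm = if (is.null(ext)) NA_real_ else ext[1],
      x_end_mm = if (is.null(ext)) NA_real_ else ext[2],
      length_mm = if (is.null(ext)) 0 else diff(ext)
    )
  })
}
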