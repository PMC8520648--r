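#' Ordered severity scales for vascular event outcomes
#'
#' An `ordinal_scale` is an ordered list of severity categories for one event
#' type, together with the rule that maps a participant's event attributes
#' (event occurred, fatal, free-text severity tag) onto a level index. Level 0
#' is always "none" (no qualifying event) and the highest level is always the
#' fatal category, so that "higher = worse" holds uniformly for trend tests,
#' cumulative-logit models and the win ratio.
#'
#' @param name scale identifier, e.g. `"stroke3"`.
#' @param levels character vector of ordered level labels, from `"none"`
#'   (index 0) up to the fatal category (index `length(levels) - 1`).
#'   Between 3 and 9 levels.
#' @param mapping named integer vector mapping non-fatal `severity_attr`
#'   tags to level indices. Defaults to mapping each intermediate level
#'   label to its own index.
#'
#' @return An object of class `ordinal_scale` with elements `name`, `levels`
#'   and `mapping`.
#' @seealso [default_scales()], [ordinalise()], [collapse_to_binary()]
#' @export
#' @examples
#' sc <- ordinal_scale("stroke3", c("none", "non-fatal stroke", "fatal stroke"))
#' n_levels(sc)
ordinal_scale <- function(name, levels, mapping = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.character(levels))
  k <- length(levels)
  if (k < 3L || k > 9L)
    stop("an ordinal scale must have between 3 and 9 levels, got ", k)
  if (levels[1L] != "none")
    stop("level 0 of scale '", name, "' must be labelled \"none\"")
  if (anyDuplicated(levels))
    stop("duplicate level labels in scale '", name, "'")
  if (is.null(mapping)) {
    idx <- seq_len(k - 2L)              # intermediate, non-fatal levels
    mapping <- stats::setNames(idx, levels[idx + 1L])
  }
  mapping <- vapply(mapping, as.integer, integer(1))
  if (any(mapping < 1L) || any(mapping > k - 1L))
    stop("mapping indices must name levels 1..", k - 1L, " of scale '", name, "'")
  structure(list(name = name, levels = levels, mapping = mapping),
            class = "ordinal_scale")
}

#' @export
print.ordinal_scale <- function(x, ...) {
  cat("Ordinal scale '", x$name, "' (", length(x$levels), " levels)\n", sep = "")
  cat("  ", paste0(seq_along(x$levels) - 1L, "=", x$levels, collapse = " < "), "\n")
  invisible(x)
}

#' Number of levels of an ordinal scale
#' @param scale an [ordinal_scale()].
#' @return integer level count.
#' @export
n_levels <- function(scale) length(scale$levels)

#' Built-in severity scales
#'
#' Default scale definitions for stroke (with and without TIA), myocardial
#' infarction, bleeding, and the composite vascular outcome. The exact level
#' definitions used for real trial exports vary between studies, so every
#' scale here can be replaced or extended through [read_scales()].
#'
#' @return named list of [ordinal_scale()] objects: `stroke3`, `strokeTIA4`,
#'   `stroke5`, `stroke8`, `mi3`, `bleed3`, `bleed4`, `bleed5`, `vascular3`.
#' @export
default_scales <- function() {
  mk <- ordinal_scale
  list(
    stroke3    = mk("stroke3",    c("none", "non-fatal stroke", "fatal stroke")),
    strokeTIA4 = mk("strokeTIA4", c("none", "TIA", "non-fatal stroke", "fatal stroke")),
    stroke5    = mk("stroke5",    c("none", "TIA", "minor stroke", "major stroke",
                                    "fatal stroke")),
    stroke8    = mk("stroke8",    c("none", "TIA", "minor stroke", "moderate stroke",
                                    "moderately severe stroke", "severe stroke",
                                    "very severe stroke", "fatal stroke")),
    mi3        = mk("mi3",        c("none", "non-fatal MI", "fatal MI")),
    bleed3     = mk("bleed3",     c("none", "major bleed", "fatal bleed")),
    bleed4     = mk("bleed4",     c("none", "minor bleed", "major bleed", "fatal bleed")),
    bleed5     = mk("bleed5",     c("none", "mild bleed", "moderate bleed",
                                    "severe bleed", "fatal bleed")),
    vascular3  = mk("vascular3",  c("none", "non-fatal stroke or MI",
                                    "fatal stroke or MI"))
  )
}

#' Map participant records to ordinal severity levels
#'
#' Deterministic construction of the ordered outcome: no event maps to level 0,
#' a fatal event to the top level, and a non-fatal event to the level named by
#' its `severity_attr` through the scale's mapping.
#'
#' @param records data frame of participant records (see
#'   [validate_participants()] for the required columns).
#' @param scale an [ordinal_scale()].
#' @return integer vector of level indices in `0:(n_levels(scale) - 1)`.
#' @export
#' @examples
#' sc <- default_scales()$strokeTIA4
#' r <- data.frame(arm = "treatment", age = 70, sex = 1, diabetes = 0,
#'                 event = 1, fatal = 0, severity_attr = "TIA",
#'                 time = 100, observed = 1)
#' ordinalise(r, sc)  # 1
ordinalise <- function(records, scale) {
  stopifnot(inherits(scale, "ordinal_scale"))
  validate_participants(records)
  k <- n_levels(scale)
  lev <- integer(nrow(records))
  lev[records$fatal == 1L] <- k - 1L
  nonfatal <- records$event == 1L & records$fatal == 0L
  if (any(nonfatal)) {
    attrs <- as.character(records$severity_attr[nonfatal])
    hit <- match(attrs, names(scale$mapping))
    if (anyNA(hit)) {
      bad <- unique(attrs[is.na(hit)])
      stop("severity_attr value(s) not mapped by scale '", scale$name, "': ",
           paste(sQuote(bad), collapse = ", "))
    }
    lev[nonfatal] <- unname(scale$mapping[hit])
  }
  lev
}

#' Collapse an ordinal level to a binary outcome
#'
#' @param level integer vector of level indices.
#' @param scale an [ordinal_scale()].
#' @param mode `"any_event"` (1 iff level > 0) or `"fatal_only"` (1 iff level
#'   is the top, fatal level).
#' @return integer 0/1 vector.
#' @export
collapse_to_binary <- function(level, scale, mode = c("any_event", "fatal_only")) {
  mode <- match.arg(mode)
  k <- n_levels(scale)
  if (any(level < 0L | level > k - 1L))
    stop("level out of range 0..", k - 1L, " for scale '", scale$name, "'")
  if (mode == "any_event") as.integer(level > 0L) else as.integer(level == k - 1L)
}

#' Read scale definitions from a YAML file
#'
#' Each top-level YAML key is a scale name holding `levels` (ordered list of
#' labels, first "none", last the fatal category) and optionally `mapping`
#' (severity tag to level index).
#'
#' @param path YAML file path.
#' @return named list of [ordinal_scale()] objects.
#' @export
read_scales <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    entry <- raw[[nm]]
    mapping <- if (!is.null(entry$mapping)) unlist(entry$mapping)
    ordinal_scale(nm, as.character(unlist(entry$levels)), mapping)
  })
  stats::setNames(out, names(raw))
}

#' Write scale definitions to a YAML file
#'
#' @param scales named list of [ordinal_scale()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scales <- function(scales, path) {
  yaml::write_yaml(lapply(scales, function(s)
    list(levels = s$levels, mapping = as.list(s$mapping))), path)
  invisible(path)
}
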