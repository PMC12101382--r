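# Screening protocols as conjunctions of directional cut-off rules.
#
# A protocol refers a newborn when EVERY criterion holds; comparisons are
# inclusive (>= / <=) as the cut-offs are printed. Historical protocols
# applied to the raw NeoBase-era SA, so criteria may reference `sa_raw`;
# everything else refers to the effective (NeoBase 2 scale) panel.

#' A directional cut-off criterion
#'
#' @param biomarker one of [panel_biomarkers()].
#' @param direction `"at_least"` (value >= cov refers) or `"at_most"`
#'   (value <= cov refers).
#' @param cov positive cut-off value in the biomarker's units.
#' @return object of class `criterion`.
#' @examples
#' criterion("tyr", "at_least", 100)
#' @export
criterion <- function(biomarker, direction = c("at_least", "at_most"), cov) {
  direction <- match.arg(direction)
  if (!biomarker %in% panel_biomarkers())
    fail("unknown biomarker '%s'; must be one of: %s", biomarker,
         paste(panel_biomarkers(), collapse = ", "))
  stopifnot(is.numeric(cov), length(cov) == 1, is.finite(cov))
  if (cov <= 0) fail("criterion: cut-off value must be > 0 (got %g)", cov)
  structure(list(biomarker = biomarker, direction = direction, cov = cov),
            class = "criterion")
}

#' @export
format.criterion <- function(x, ...) {
  sprintf("%s %s %g", x$biomarker,
          if (x$direction == "at_least") ">=" else "<=", x$cov)
}

#' @export
print.criterion <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' A screening protocol (conjunction of criteria)
#'
#' @param name protocol label.
#' @param criteria a [criterion()] or non-empty list of them; no two
#'   criteria may share the same biomarker and direction.
#' @param provenance one of `"historical"`, `"current"`, `"alternative"`,
#'   `"user"`.
#' @return object of class `protocol`.
#' @export
protocol <- function(name, criteria,
                     provenance = c("user", "historical", "current", "alternative")) {
  provenance <- match.arg(provenance)
  if (inherits(criteria, "criterion")) criteria <- list(criteria)
  if (!length(criteria)) fail("protocol '%s' has no criteria", name)
  if (!all(vapply(criteria, inherits, TRUE, "criterion")))
    fail("protocol '%s': criteria must be criterion objects", name)
  key <- vapply(criteria, function(cr) paste(cr$biomarker, cr$direction), "")
  if (anyDuplicated(key))
    fail("protocol '%s': duplicate criterion on %s", name, key[duplicated(key)][1])
  structure(list(name = name, criteria = criteria, provenance = provenance),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("Screening protocol '%s' (%s):\n", x$name, x$provenance))
  for (cr in x$criteria) cat("  ", format(cr), "\n")
  invisible(x)
}

# canonical signature used for deduplication
protocol_signature <- function(p) {
  paste(sort(vapply(p$criteria, function(cr)
    sprintf("%s|%s|%.12g", cr$biomarker, cr$direction, cr$cov), "")),
    collapse = ";")
}

#' Classify panel records under a protocol
#'
#' A record is screen-positive iff every criterion holds; comparisons are
#' inclusive, so a value exactly at the cut-off refers. A criterion whose
#' biomarker is undefined for a record (zero-denominator ratio, `NA`) makes
#' the record unclassifiable unless another criterion already fails; such
#' records raise an error rather than being silently screen-negative.
#'
#' @param panel output of [compute_panel()].
#' @param protocol a [protocol()].
#' @return character vector, `"screen_positive"` / `"screen_negative"`.
#' @export
classify <- function(panel, protocol) {
  stopifnot(is.data.frame(panel), inherits(protocol, "protocol"))
  pass <- vapply(protocol$criteria, function(cr) {
    if (is.null(panel[[cr$biomarker]]))
      fail("protocol '%s': panel lacks biomarker '%s'",
           protocol$name, cr$biomarker)
    v <- panel[[cr$biomarker]]
    if (cr$direction == "at_least") v >= cr$cov else v <= cr$cov
  }, logical(nrow(panel)))
  pass <- matrix(pass, nrow = nrow(panel))
  any_fail <- rowSums(!pass, na.rm = TRUE) > 0
  unresolved <- rowSums(is.na(pass)) > 0 & !any_fail
  if (any(unresolved))
    fail("protocol '%s': undefined biomarker value(s) leave record(s) %s unclassified",
         protocol$name,
         paste(utils::head(panel$record_id[unresolved], 10), collapse = ", "))
  ifelse(any_fail, "screen_negative", "screen_positive")
}

#' Catalogue of built-in screening protocols
#'
#' The Dutch programme's historical and current rules plus the three
#' best-performing published alternatives:
#' \describe{
#'   \item{tyr500_2007}{tyrosine >= 500 umol/L (Jan-Feb 2007).}
#'   \item{sa15_2008}{raw NeoBase SA >= 1.5 umol/L (Oct 2008 - Jun 2009).}
#'   \item{sa12_2009}{raw NeoBase SA >= 1.2 umol/L (Jul 2009 - Dec 2017).}
#'   \item{sa090_2018}{raw SA >= 0.90 umol/L (Jan 2018 - Mar 2019).}
#'   \item{sa060_current}{effective SA >= 0.60 umol/L (since Apr 2019).}
#'   \item{alt_L}{SA >= 0.60, tyr >= 100, tyr x SA >= 100, tyr/phe >= 2.5.}
#'   \item{alt_N}{SA >= 0.60, tyr >= 100, tyr x SA >= 110, phe/tyr <= 0.5.}
#'   \item{alt_O}{SA >= 0.60, tyr >= 100, tyr x SA >= 110, tyr/phe >= 2.5.}
#' }
#' Historical-era rules reference `sa_raw` (the scale on which they were
#' applied); the current rule and alternatives reference the effective SA.
#'
#' @return named list of [protocol()] objects.
#' @export
builtin_protocols <- function() {
  ge <- function(b, v) criterion(b, "at_least", v)
  le <- function(b, v) criterion(b, "at_most", v)
  list(
    tyr500_2007 = protocol("tyr500_2007", ge("tyr", 500), "historical"),
    sa15_2008 = protocol("sa15_2008", ge("sa_raw", 1.5), "historical"),
    sa12_2009 = protocol("sa12_2009", ge("sa_raw", 1.2), "historical"),
    sa090_2018 = protocol("sa090_2018", ge("sa_raw", 0.90), "historical"),
    sa060_current = protocol("sa060_current", ge("sa_eff", 0.60), "current"),
    alt_L = protocol("alt_L", list(ge("sa_eff", 0.60), ge("tyr", 100),
                                   ge("tyr_times_sa", 100), ge("tyr_over_phe", 2.5)),
                     "alternative"),
    alt_N = protocol("alt_N", list(ge("sa_eff", 0.60), ge("tyr", 100),
                                   ge("tyr_times_sa", 110), le("phe_over_tyr", 0.5)),
                     "alternative"),
    alt_O = protocol("alt_O", list(ge("sa_eff", 0.60), ge("tyr", 100),
                                   ge("tyr_times_sa", 110), ge("tyr_over_phe", 2.5)),
                     "alternative")
  )
}

#' Derive a cut-off value from confirmed-patient biomarker values
#'
#' Cut-offs for biomarkers other than SA are anchored to the most extreme
#' value observed among confirmed patients, with a safety margin so no known
#' patient sits on the edge: for `at_least` the cut-off is the largest
#' multiple of `granularity` strictly below the patient minimum (falling
#' back to the minimum itself when no positive multiple exists); for
#' `at_most` it is the smallest multiple at or above the patient maximum,
#' plus one further step. The derived cut-off never excludes any supplied
#' patient value.
#'
#' @param tp_values biomarker values of confirmed patients (non-empty).
#' @param direction `"at_least"` or `"at_most"`.
#' @param granularity positive step size of the cut-off grid.
#' @return a cut-off value on the granularity grid (or the patient extreme).
#' @examples
#' derive_cov(c(829, 439, 288, 112), "at_least", 50)   # 100
#' derive_cov(c(0.10, 0.24, 0.38), "at_most", 0.1)     # 0.5
#' @export
derive_cov <- function(tp_values, direction = c("at_least", "at_most"),
                       granularity) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(tp_values), is.numeric(granularity),
            length(granularity) == 1)
  if (!length(tp_values)) fail("derive_cov: empty patient value list")
  if (anyNA(tp_values)) fail("derive_cov: NA in patient values")
  if (granularity <= 0) fail("derive_cov: granularity must be > 0")
  g <- granularity
  if (direction == "at_least") {
    lo <- min(tp_values)
    cov <- floor((lo - g * 1e-6) / g) * g
    if (cov <= 0) cov <- lo  # no room for a margin on the grid
  } else {
    hi <- max(tp_values)
    cov <- (ceiling((hi - g * 1e-6) / g) + 1) * g
  }
  cov
}

#' Enumerate alternative screening protocols from a candidate grid
#'
#' Builds the evaluated protocol set: singleton protocols (one candidate
#' criterion each, with varied cut-offs) and conjunction protocols that keep
#' the SA base criterion and add one candidate set of criteria. Protocols
#' identical up to their (biomarker, direction, cut-off) multiset are
#' deduplicated.
#'
#' @param base the SA base [criterion()]; default effective SA >= 0.60, the
#'   cut-off maintained in all combination protocols.
#' @param singletons list of [criterion()] objects, one protocol each.
#' @param addon_sets list of criterion lists; each yields `base + addons`.
#' @return named list of [protocol()] objects.
#' @seealso [default_alternative_grid()] for the shipped reconstruction of
#'   the evaluated 30-protocol design.
#' @export
enumerate_alternatives <- function(base = criterion("sa_eff", "at_least", 0.60),
                                   singletons = list(), addon_sets = list()) {
  stopifnot(inherits(base, "criterion"))
  if (!length(singletons) && !length(addon_sets))
    fail("enumerate_alternatives: empty candidate grid")
  protos <- list()
  for (i in seq_along(singletons)) {
    cr <- singletons[[i]]
    p <- protocol(sprintf("single_%02d_%s", i, cr$biomarker), cr, "alternative")
    protos[[p$name]] <- p
  }
  for (i in seq_along(addon_sets)) {
    crs <- addon_sets[[i]]
    if (inherits(crs, "criterion")) crs <- list(crs)
    p <- protocol(sprintf("combo_%02d", i), c(list(base), crs), "alternative")
    protos[[p$name]] <- p
  }
  sigs <- vapply(protos, protocol_signature, "")
  protos[!duplicated(sigs)]
}

#' Default candidate grid for alternative protocols
#'
#' A reconstruction of the evaluated design: 13 singleton protocols (single
#' biomarkers at varied cut-offs) and 17 combination protocols that keep
#' the SA >= 0.60 base. The exact published grid is not public beyond its
#' size and its three best members, so this grid is anchored to the
#' patient-derived cut-offs (tyr 100; tyr x SA 100/110; tyr/phe 2.5;
#' phe/tyr 0.5) and contains the three published best combinations exactly.
#'
#' @return list with elements `base`, `singletons` and `addon_sets`,
#'   suitable for [enumerate_alternatives()].
#' @export
default_alternative_grid <- function() {
  ge <- function(b, v) criterion(b, "at_least", v)
  le <- function(b, v) criterion(b, "at_most", v)
  list(
    base = ge("sa_eff", 0.60),
    singletons = list(
      ge("tyr", 100), ge("tyr", 200), ge("tyr", 500),
      le("phe", 150),
      ge("tyr_times_sa", 100), ge("tyr_times_sa", 110), ge("tyr_times_sa", 150),
      ge("tyr_over_sa", 20),
      le("sa_over_tyr", 0.05),
      ge("sa_over_phe", 0.005),
      ge("tyr_over_phe", 2.5), ge("tyr_over_phe", 4),
      le("phe_over_tyr", 0.5)
    ),
    addon_sets = list(
      list(ge("tyr", 100)),
      list(le("phe", 150)),
      list(ge("tyr_times_sa", 100)),
      list(ge("tyr_times_sa", 110)),
      list(ge("tyr_over_sa", 20)),
      list(le("sa_over_tyr", 0.05)),
      list(ge("sa_over_phe", 0.005)),
      list(ge("tyr_over_phe", 2.5)),
      list(le("phe_over_tyr", 0.5)),
      list(ge("tyr", 100), ge("tyr_times_sa", 100)),
      list(ge("tyr", 100), ge("tyr_times_sa", 110)),
      list(ge("tyr", 100), ge("tyr_over_phe", 2.5)),
      list(ge("tyr", 100), le("phe_over_tyr", 0.5)),
      list(ge("tyr", 100), ge("tyr_times_sa", 100), ge("tyr_over_phe", 2.5)),  # = alt_L
      list(ge("tyr", 100), ge("tyr_times_sa", 110), le("phe_over_tyr", 0.5)),  # = alt_N
      list(ge("tyr", 100), ge("tyr_times_sa", 110), ge("tyr_over_phe", 2.5)),  # = alt_O
      list(ge("tyr", 100), ge("tyr_times_sa", 100), le("phe_over_tyr", 0.5))
    )
  )
}

#' Write / read protocols as a plain text config
#'
#' One block per protocol: a `[name]` header followed by one line per
#' criterion, `<biomarker> <ge|le> <value>`. Round-trips losslessly.
#'
#' @param protocols named list of [protocol()] objects.
#' @param path file path.
#' @return `write_protocols` returns `path` invisibly; `read_protocols`
#'   returns a named list of protocols (provenance `"user"`).
#' @export
write_protocols <- function(protocols, path) {
  if (inherits(protocols, "protocol")) protocols <- list(protocols)
  lines <- unlist(lapply(protocols, function(p) {
    c(sprintf("[%s]", p$name),
      vapply(p$criteria, function(cr)
        sprintf("%s %s %.12g", cr$biomarker,
                if (cr$direction == "at_least") "ge" else "le", cr$cov), ""),
      "")
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_protocols
#' @export
read_protocols <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  protos <- list()
  name <- NULL
  crs <- list()
  flush <- function() {
    if (!is.null(name)) {
      if (!length(crs)) fail("protocol block '%s' has no criteria", name)
      protos[[name]] <<- protocol(name, crs, "user")
    }
  }
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      flush()
      name <- sub("^\\[(.+)\\]$", "\\1", ln)
      crs <- list()
    } else {
      parts <- strsplit(ln, "\\s+")[[1]]
      if (length(parts) != 3 || !parts[2] %in% c("ge", "le"))
        fail("malformed criterion line: '%s'", ln)
      crs[[length(crs) + 1]] <- criterion(
        parts[1], if (parts[2] == "ge") "at_least" else "at_most",
        as.numeric(parts[3]))
    }
  }
  flush()
  protos
}
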