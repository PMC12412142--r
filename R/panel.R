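# Reference-compound panels: loading, validation and the bundled default.

#' Read a reference-compound panel from CSV
#'
#' A panel CSV has columns `name, formula, adduct, polarity, expected_mz,
#' nominal_label, log_kow, cid, cas` (and optionally `erratum`). `adduct`
#' must be `+H` or `-H`; `polarity` (`POS`/`NEG`), when present, must match
#' the adduct sign. `expected_mz` may be left empty, in which case the
#' theoretical adduct m/z is computed from the formula. A computed m/z that
#' disagrees with a supplied `expected_mz` by more than `mz_tol` u is an
#' error unless the row is flagged `erratum = TRUE`, in which case the
#' supplied value is kept verbatim (a documented literature value takes
#' precedence over the formula).
#'
#' @param path Path to the panel CSV.
#' @param name Panel name; defaults to the file name.
#' @param mz_tol Agreement tolerance between computed and supplied
#'   expected m/z, in u.
#' @return A data frame of class `sst_panel` with an added `computed_mz`
#'   column.
#' @seealso [default_panel()], [validate_panel()]
#' @export
read_panel <- function(path, name = basename(path), mz_tol = 5e-4) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("name", "formula", "adduct")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("panel file lacks required column(s): ", paste(missing, collapse = ", "))
  if (!nrow(df)) stop("panel file has no compounds")
  if (anyDuplicated(df$name))
    stop("duplicate compound name(s): ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  df$adduct <- gsub("–|−", "-", df$adduct)
  bad <- setdiff(unique(df$adduct), c("+H", "-H"))
  if (length(bad))
    stop("unsupported adduct(s): ", paste(bad, collapse = ", "))
  pol_from_adduct <- ifelse(df$adduct == "+H", "POS", "NEG")
  if (!"polarity" %in% names(df) || all(is.na(df$polarity))) {
    df$polarity <- pol_from_adduct
  } else if (any(df$polarity != pol_from_adduct)) {
    stop("polarity inconsistent with adduct for: ",
         paste(df$name[df$polarity != pol_from_adduct], collapse = ", "))
  }
  if (!"erratum" %in% names(df)) df$erratum <- FALSE
  df$erratum <- as.logical(df$erratum)
  df$erratum[is.na(df$erratum)] <- FALSE
  for (col in c("expected_mz", "log_kow")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- as.numeric(df[[col]])
  }
  if (!"nominal_label" %in% names(df)) df$nominal_label <- NA_integer_
  for (col in c("cid", "cas")) if (!col %in% names(df)) df[[col]] <- NA_character_

  df$computed_mz <- vapply(seq_len(nrow(df)), function(i)
    adduct_mz(df$formula[i], df$adduct[i]), numeric(1))
  fill <- is.na(df$expected_mz)
  df$expected_mz[fill] <- round(df$computed_mz[fill], 4)
  off <- abs(df$computed_mz - df$expected_mz) > mz_tol & !df$erratum
  if (any(off))
    stop("expected m/z disagrees with formula + adduct for: ",
         paste(sprintf("%s (computed %.4f, expected %.4f)",
                       df$name[off], df$computed_mz[off], df$expected_mz[off]),
               collapse = "; "),
         "; flag the row as erratum to keep the supplied value")
  structure(df, panel_name = name, class = c("sst_panel", "data.frame"))
}

#' The bundled 13-compound HRAM-SST panel
#'
#' Thirteen reference standards spanning both electrospray polarities and
#' a wide m/z range (152-716 in positive mode, 263-498 in negative mode):
#' eight protonated (`+H`) and five deprotonated (`-H`) species, covering
#' pharmaceuticals, a macrolide, and several perfluoroalkyl acids. One
#' entry (perfluoropentanoic acid) carries a documented erratum: its
#' published expected m/z (262.9760) corresponds to C5HF9O2 rather than
#' the listed formula C6HF9O2, and the published value is kept with the
#' `erratum` flag set.
#'
#' @return An `sst_panel` data frame with 13 rows.
#' @examples
#' p <- default_panel()
#' table(p$polarity)
#' @export
default_panel <- function() {
  read_panel(system.file("extdata", "hram_sst_panel.csv", package = "hramsst",
                         mustWork = TRUE),
             name = "HRAM-SST default panel")
}

#' @export
print.sst_panel <- function(x, ...) {
  cat(sprintf("<sst_panel> %s: %d compounds (%d POS, %d NEG)\n",
              attr(x, "panel_name"), nrow(x),
              sum(x$polarity == "POS"), sum(x$polarity == "NEG")))
  print.data.frame(x[, c("name", "formula", "adduct", "polarity",
                         "expected_mz", "erratum")], row.names = FALSE)
  invisible(x)
}

#' Advisory panel design checks
#'
#' Screens a panel against the design guidance for SST mixtures: compounds
#' should tile the acquisition scan range at roughly one compound per
#' 100-200 m/z per polarity. Reports, per polarity, gaps between
#' neighbouring compounds larger than `max_gap` u, uncovered stretches at
#' either end of the scan range (more than `edge_gap` u without a
#' compound), compounds falling outside the scan range, duplicate masses,
#' and erratum flags. Findings are purely advisory; this never fails.
#'
#' @param panel An `sst_panel`.
#' @param mz_min,mz_max Acquisition scan range in u (default 100-1000,
#'   a typical small-molecule full-scan window).
#' @param max_gap Largest acceptable gap between neighbouring panel masses, u.
#' @param edge_gap Largest acceptable uncovered stretch at the range ends, u.
#' @return A data frame of class `sst_panel_findings` with columns
#'   `type`, `polarity`, `message` (zero rows when the design is clean).
#' @export
validate_panel <- function(panel, mz_min = 100, mz_max = 1000,
                           max_gap = 200, edge_gap = 100) {
  stopifnot(inherits(panel, "sst_panel"), mz_min < mz_max)
  findings <- list()
  add <- function(type, polarity, message)
    findings[[length(findings) + 1L]] <<- data.frame(
      type = type, polarity = polarity, message = message,
      stringsAsFactors = FALSE)

  out <- panel$expected_mz < mz_min | panel$expected_mz > mz_max
  for (i in which(out))
    add("out_of_range", panel$polarity[i],
        sprintf("%s (m/z %.4f) is outside the scan range %g-%g",
                panel$name[i], panel$expected_mz[i], mz_min, mz_max))

  for (pol in c("POS", "NEG")) {
    mz <- sort(panel$expected_mz[panel$polarity == pol & !out])
    if (!length(mz)) {
      add("no_coverage", pol, sprintf("no %s compounds in range", pol))
      next
    }
    if (mz[1] - mz_min > edge_gap)
      add("edge_gap", pol,
          sprintf("no %s compound below m/z %.0f (range starts at %g)",
                  pol, floor(mz[1]), mz_min))
    if (mz_max - mz[length(mz)] > edge_gap)
      add("edge_gap", pol,
          sprintf("no %s compound above m/z %.0f (range ends at %g)",
                  pol, ceiling(mz[length(mz)]), mz_max))
    if (length(mz) > 1) {
      gaps <- diff(mz)
      for (j in which(gaps > max_gap))
        add("gap", pol,
            sprintf("%.0f u gap between m/z %.4f and %.4f (> %g)",
                    gaps[j], mz[j], mz[j + 1], max_gap))
      dup <- which(gaps < 0.01)
      for (j in dup)
        add("duplicate_mass", pol,
            sprintf("near-duplicate masses %.4f and %.4f", mz[j], mz[j + 1]))
    }
  }
  for (i in which(panel$erratum))
    add("erratum", panel$polarity[i],
        sprintf("%s: published expected m/z %.4f kept despite disagreeing with formula %s (computed %.4f)",
                panel$name[i], panel$expected_mz[i], panel$formula[i],
                panel$computed_mz[i]))

  res <- if (length(findings)) do.call(rbind, findings) else
    data.frame(type = character(), polarity = character(),
               message = character(), stringsAsFactors = FALSE)
  structure(res, class = c("sst_panel_findings", "data.frame"))
}

#' @export
print.sst_panel_findings <- function(x, ...) {
  if (!nrow(x)) {
    cat("No panel design findings.\n")
  } else {
    cat(nrow(x), "panel design finding(s):\n")
    for (i in seq_len(nrow(x)))
      cat(sprintf(" - [%s/%s] %s\n", x$polarity[i], x$type[i], x$message[i]))
  }
  invisible(x)
}
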