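#' Globally unique family keys
#'
#' The per-parish FRF reference numbers are made globally unique by
#' prepending a short textual parish code to the number padded with leading
#' zeroes, so keys remain order-preserving within a parish.
#'
#' @param parish_code short textual parish code, e.g. `"ALC"`.
#' @param frf_number positive integer FRF reference number (vectorised).
#' @param pad_width zero-padding width; must accommodate the largest number.
#' @return Character vector of parfrf keys.
#' @examples
#' make_parfrf("BAN", 17, 6)  # "BAN000017"
#' @export
make_parfrf <- function(parish_code, frf_number, pad_width = 6L) {
  frf_number <- as.integer(frf_number)
  if (any(is.na(frf_number) | frf_number < 1L))
    stop("make_parfrf: frf_number must be a positive integer")
  if (any(nchar(as.character(frf_number)) > pad_width))
    stop("make_parfrf: pad_width ", pad_width,
         " too small for frf_number ", max(frf_number))
  sprintf("%s%0*d", parish_code, as.integer(pad_width), frf_number)
}

# Parse + normalize a vector of raw date tokens; primary and bracketed
# secondary are returned as separate Date/weighting columns (paired dates
# become separate database fields).
.date_cols <- function(tokens, context = "date") {
  n <- length(tokens)
  p <- .parse_wd_vec(tokens)
  if (any(!p$ok))
    stop("malformed ", context, " token ",
         sQuote(tokens[which(!p$ok)[1L]]))
  out <- list(date = rep(as.Date(NA), n), weighting = rep(NA_integer_, n),
              secondary_date = rep(as.Date(NA), n),
              secondary_weighting = rep(NA_integer_, n))
  pr <- which(!is.na(p$year))
  if (length(pr)) {
    r <- .normalize_dmyw(p$day[pr], p$month[pr], p$year[pr], p$weighting[pr])
    out$date[pr] <- as.Date(sprintf("%04d-%02d-%02d",
                                    r$year, r$month, r$day))
    out$weighting[pr] <- r$weighting
  }
  sc <- which(!is.na(p$s_year))
  if (length(sc)) {
    r <- .normalize_dmyw(p$s_day[sc], p$s_month[sc], p$s_year[sc],
                         rep(NA_integer_, length(sc)))
    out$secondary_date[sc] <- as.Date(sprintf("%04d-%02d-%02d",
                                              r$year, r$month, r$day))
    out$secondary_weighting[sc] <- r$weighting
  }
  out
}

.int_col <- function(tokens) {
  tokens[tokens == "-"] <- NA_character_
  suppressWarnings(as.integer(tokens))
}

.chr_col <- function(tokens) {
  tokens[tokens == "-"] <- NA_character_
  tokens
}

# Pre-index each record's lines by class so field extraction is plain list
# indexing rather than a scan per field.
.pre_index <- function(records) {
  lapply(records, function(r) {
    cls <- vapply(r$lines, `[[`, "", "class")
    li <- vector("list", 0L)
    for (c1 in c("M", "H", "W", "HM", "HF", "WM", "WF", "L")) {
      j <- which(cls == c1)
      if (length(j)) li[[c1]] <- r$lines[[j[1L]]]$fields
    }
    li$C <- lapply(which(cls == "C"), function(j) r$lines[[j]]$fields)
    li
  })
}

# combined raw flag strings looked up by (record index, class, instance)
.flag_index <- function(records) {
  rec <- integer(); cls <- character(); idx <- integer(); raw <- character()
  for (i in seq_along(records)) {
    for (fa in records[[i]]$flags) {
      rec <- c(rec, i); cls <- c(cls, fa$target_class)
      idx <- c(idx, fa$target_index); raw <- c(raw, fa$raw)
    }
  }
  if (!length(rec)) return(function(recs, cls, idx)
    rep(NA_character_, length(recs)))
  key <- paste(rec, cls, idx)
  tab <- tapply(raw, key, paste, collapse = ",")
  function(recs, cls, idx) {
    v <- tab[paste(recs, cls, idx)]
    unname(v)
  }
}

.has_code <- function(flag_string, code) {
  if (!length(flag_string)) return(logical())
  s <- flag_string
  s[is.na(s)] <- ""
  vapply(strsplit(s, ",", fixed = TRUE),
         function(v) any(grepl(code, v, fixed = TRUE)), TRUE)
}

# field extractor over the pre-index: one vapply per (class, position)
.gf <- function(pre, cls, pos) {
  vapply(pre, function(p) {
    f <- p[[cls]]
    if (is.null(f) || pos > length(f)) "-" else f[[pos]]
  }, "")
}

.spouse_table <- function(pre, parfrf, cls, layout, flag_for) {
  lay <- layout[[cls]]
  tok <- function(name) .gf(pre, cls, match(name, lay))
  bap <- .date_cols(tok("baptism_date"), paste0(cls, " baptism"))
  bur <- .date_cols(tok("burial_date"), paste0(cls, " burial"))
  fl <- flag_for(seq_along(pre), cls, 1L)
  has_line <- !vapply(pre, function(p) is.null(p[[cls]]), TRUE)
  df <- data.frame(
    parfrf = parfrf,
    role = cls,
    name = .chr_col(tok("name")),
    baptism_date = bap$date, baptism_weighting = bap$weighting,
    birth_date = bap$secondary_date,
    birth_weighting = bap$secondary_weighting,
    burial_date = bur$date, burial_weighting = bur$weighting,
    death_date = bur$secondary_date,
    death_weighting = bur$secondary_weighting,
    birthplace = .chr_col(tok("birthplace")),
    occupation = .chr_col(tok("occupation")),
    earlier_frf = .int_col(tok("earlier_frf")),
    later_frf = .int_col(tok("later_frf")),
    widowed = .has_code(fl, "W"),
    flags = fl,
    stringsAsFactors = FALSE
  )
  df[has_line, , drop = FALSE]
}

.parent_table <- function(pre, parfrf, cls, layout, flag_for) {
  lay <- layout[[cls]]
  has_line <- !vapply(pre, function(p) is.null(p[[cls]]), TRUE)
  tok <- function(name) .gf(pre, cls, match(name, lay))
  df <- data.frame(parfrf = parfrf, role = cls,
                   name = .chr_col(tok("name")),
                   stringsAsFactors = FALSE)
  if ("residence" %in% lay) df$residence <- .chr_col(tok("residence"))
  if ("occupation" %in% lay) df$occupation <- .chr_col(tok("occupation"))
  df$flags <- flag_for(seq_along(pre), cls, 1L)
  df[has_line, , drop = FALSE]
}

#' Convert parsed FRF records to the nine-table relational bundle
#'
#' Each line class becomes a table: marriages, husbands, wives, children,
#' the four parent tables, and literacy. Flag assignments are appended to
#' whichever rows they referenced (widowhood, stillbirth and twin codes get
#' indicator columns; the raw compound flag strings are retained verbatim).
#' Paired dates are split into separate fields (baptism/birth,
#' burial/death), all dates are calendar-normalized via
#' [normalize_date()] with weightings kept in their own columns, and absent
#' values are explicit `NA`s. Children are numbered 1..n in input order.
#'
#' @param records list of [frf_record()]s for one parish.
#' @param parish_code short textual parish code used to build parfrf keys.
#' @param pad_width zero-padding width for [make_parfrf()].
#' @param layout per-parish line layout, see [default_frf_layout()].
#' @return An object of class `frf_bundle`: a list of nine data.frames with
#'   attributes `parish_code` and `pad_width`.
#' @export
records_to_bundle <- function(records, parish_code,
                              pad_width = 6L,
                              layout = default_frf_layout()) {
  frf <- vapply(records, `[[`, 0L, "frf_number")
  parfrf <- make_parfrf(parish_code, frf, pad_width)
  if (anyDuplicated(parfrf))
    stop("records_to_bundle: duplicate parfrf ",
         parfrf[duplicated(parfrf)][1L],
         "; resolve duplicate FRF numbers before conversion")
  pre <- .pre_index(records)
  flag_for <- .flag_index(records)

  mlay <- layout$M
  mtok <- function(name) .gf(pre, "M", match(name, mlay) + 1L)  # skip frf no.
  mdate <- .date_cols(mtok("marriage_date"), "marriage date")
  marriages <- data.frame(
    parfrf = parfrf, frf_number = frf,
    marriage_date = mdate$date, marriage_weighting = mdate$weighting,
    marriage_place = .chr_col(mtok("marriage_place")),
    stringsAsFactors = FALSE)

  husbands <- .spouse_table(pre, parfrf, "H", layout, flag_for)
  wives <- .spouse_table(pre, parfrf, "W", layout, flag_for)

  ## children: flatten all C lines, numbered within each record
  clay <- layout$C
  nkids <- vapply(pre, function(p) length(p$C), 0L)
  ch_rec <- rep(seq_along(pre), nkids)
  ch_num <- unlist(lapply(nkids, seq_len), use.names = FALSE)
  if (is.null(ch_num)) ch_num <- integer()
  ch_fields <- unlist(lapply(pre, `[[`, "C"), recursive = FALSE)
  ctok <- function(name) {
    pos <- match(name, clay)
    if (!length(ch_fields)) return(character())
    vapply(ch_fields, function(f)
      if (pos > length(f)) "-" else f[[pos]], "")
  }
  cbap <- .date_cols(ctok("baptism_date"), "child baptism")
  cbur <- .date_cols(ctok("burial_date"), "child burial")
  cmar <- .date_cols(ctok("marriage_date"), "child marriage")
  cfl <- flag_for(ch_rec, "C", ch_num)
  if (is.null(cfl)) cfl <- character()
  children <- data.frame(
    parfrf = parfrf[ch_rec], child_number = ch_num,
    name = .chr_col(ctok("name")),
    sex = .chr_col(ctok("sex")),
    baptism_date = cbap$date, baptism_weighting = cbap$weighting,
    birth_date = cbap$secondary_date,
    birth_weighting = cbap$secondary_weighting,
    burial_date = cbur$date, burial_weighting = cbur$weighting,
    death_date = cbur$secondary_date,
    death_weighting = cbur$secondary_weighting,
    marriage_date = cmar$date, marriage_weighting = cmar$weighting,
    own_frf = .int_col(ctok("own_frf")),
    stillborn = .has_code(cfl, "Z"),
    twin = .has_code(cfl, "2"),
    flags = cfl,
    stringsAsFactors = FALSE)

  llay <- layout$L
  has_l <- !vapply(pre, function(p) is.null(p$L), TRUE)
  ltok <- function(name) .gf(pre, "L", match(name, llay))
  literacy <- data.frame(parfrf = parfrf,
                         husband_signs = .chr_col(ltok("husband_signs")),
                         wife_signs = .chr_col(ltok("wife_signs")),
                         stringsAsFactors = FALSE)[has_l, , drop = FALSE]

  bundle <- structure(list(
    marriages = marriages,
    husbands = husbands,
    wives = wives,
    children = children,
    husbands_fathers = .parent_table(pre, parfrf, "HF", layout, flag_for),
    husbands_mothers = .parent_table(pre, parfrf, "HM", layout, flag_for),
    wives_fathers = .parent_table(pre, parfrf, "WF", layout, flag_for),
    wives_mothers = .parent_table(pre, parfrf, "WM", layout, flag_for),
    literacy = literacy
  ), class = "frf_bundle",
     parish_code = parish_code, pad_width = as.integer(pad_width))
  bundle
}

#' @export
print.frf_bundle <- function(x, ...) {
  cat("<frf_bundle> parish", attr(x, "parish_code"), "-",
      nrow(x$marriages), "marriages,", nrow(x$children), "children\n")
  invisible(x)
}

#' Resolve cross-family record links
#'
#' Husband and wife rows may point to earlier or later marriages of the same
#' person, and child rows to the family the child later formed (its own
#' first marriage). Links are within-parish FRF numbers; each is resolved to
#' a parfrf or reported as dangling (never fatal).
#'
#' @param bundle an `frf_bundle`.
#' @return A data.frame with columns `parfrf`, `role` (`H`, `W` or `Cxx`),
#'   `link_kind` (`earlier_marriage`, `later_marriage`,
#'   `own_first_marriage`), `target_frf`, `target_parfrf`, `resolved`.
#' @export
resolve_links <- function(bundle) {
  stopifnot(inherits(bundle, "frf_bundle"))
  parish <- attr(bundle, "parish_code")
  pad <- attr(bundle, "pad_width")
  out <- list()
  add <- function(parfrf, role, kind, target_frf) {
    keep <- !is.na(target_frf)
    if (!any(keep)) return()
    out[[length(out) + 1L]] <<- data.frame(
      parfrf = parfrf[keep], role = role[keep], link_kind = kind,
      target_frf = target_frf[keep],
      stringsAsFactors = FALSE)
  }
  for (tab in c("husbands", "wives")) {
    t <- bundle[[tab]]
    add(t$parfrf, t$role, "earlier_marriage", t$earlier_frf)
    add(t$parfrf, t$role, "later_marriage", t$later_frf)
  }
  ch <- bundle$children
  add(ch$parfrf, sprintf("C%02d", ch$child_number), "own_first_marriage",
      ch$own_frf)
  if (!length(out))
    return(data.frame(parfrf = character(), role = character(),
                      link_kind = character(), target_frf = integer(),
                      target_parfrf = character(), resolved = logical(),
                      stringsAsFactors = FALSE))
  links <- do.call(rbind, out)
  links$target_parfrf <- make_parfrf(parish, links$target_frf, pad)
  links$resolved <- links$target_parfrf %in% bundle$marriages$parfrf
  rownames(links) <- NULL
  links
}

#' Write a relational bundle to CSV files
#'
#' One CSV per table plus a `links.csv`; `NA` values are written as empty
#' fields.
#'
#' @param bundle an `frf_bundle`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(bundle)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(bundle[[nm]], p, row.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  p <- file.path(dir, "links.csv")
  utils::write.csv(resolve_links(bundle), p, row.names = FALSE, na = "")
  invisible(c(paths, p))
}
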