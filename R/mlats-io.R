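#' Default videotranslation palette
#'
#' The palette is the controlled vocabulary a videotranslator uses when
#' converting footage to micro-level activity time series (MLATS): a set of
#' location tokens, a set of object/surface tokens, and the two activity
#' types (`constant`, `repetitive`). Object vocabularies differ slightly by
#' body part: the mouth palette offers `Hands` as a mouthable object while
#' the hand palettes offer `Mouth` as a touchable object.
#'
#' `Not_In_View` is a reserved object token marking an observation gap: it
#' contributes elapsed time but is excluded from contact counts by default.
#'
#' @return A list with elements `locations`, `objects`, `activity_types`,
#'   `not_in_view_token`, and `no_contact_token`.
#' @export
#' @examples
#' pal <- default_palette()
#' "Pacifier" %in% pal$objects
default_palette <- function() {
  list(
    locations = c(
      "Bedroom", "Kitchen", "Living_Room", "Bathroom", "Dining_Room",
      "Playroom", "Hallway", "Outdoor", "Yard", "Patio", "Porch", "Other"
    ),
    objects = c(
      "Nothing", "Hands", "Mouth", "Pacifier", "Electronics", "Hard_Toy",
      "Soft_Toy", "Clothing", "Sticky_Food", "Non_Sticky_Food", "Floor",
      "Carpet", "Furniture", "Fabric", "Paper", "Skin", "Animal", "Metal",
      "Plastic", "Wood", "Vegetation", "Soil", "Not_In_View"
    ),
    activity_types = c("constant", "repetitive"),
    not_in_view_token = "Not_In_View",
    no_contact_token = "Nothing"
  )
}

#' Read or write a palette file
#'
#' Palettes are stored as YAML (the canonical structured-config format used
#' throughout the package) so study teams can extend the object vocabulary
#' (e.g. adding `Pacifier` or `Electronics`) without code changes.
#'
#' @param path File path.
#' @param palette A palette list as from [default_palette()].
#' @return `read_palette()` returns a palette list; `write_palette()` returns
#'   `path` invisibly.
#' @export
read_palette <- function(path) {
  pal <- yaml::read_yaml(path)
  needed <- c("locations", "objects", "activity_types")
  missing <- setdiff(needed, names(pal))
  if (length(missing) > 0) {
    stop("palette file missing field(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(pal$not_in_view_token)) pal$not_in_view_token <- "Not_In_View"
  if (is.null(pal$no_contact_token)) pal$no_contact_token <- "Nothing"
  pal
}

#' @rdname read_palette
#' @export
write_palette <- function(palette, path) {
  yaml::write_yaml(palette, path)
  invisible(path)
}

#' Construct an MLATS series
#'
#' An `mlats_series` holds the validated, strictly sequential contact records
#' of one body part (left hand, right hand, or mouth) for one child. Records
#' carry an activity type (`constant` or `repetitive`), a location token, an
#' object/surface token, and a positive duration in seconds. Records tile the
#' observation window: record k starts where record k-1 ended.
#'
#' @param records A data frame with columns `activity_type`, `location`,
#'   `object_surface`, `duration_s`.
#' @param body_part One of `"left_hand"`, `"right_hand"`, `"mouth"`.
#' @param child_id Identifier string.
#' @param palette Palette list; see [default_palette()].
#' @param strict If `TRUE`, unknown palette tokens are an error; otherwise a
#'   warning.
#' @return An object of class `mlats_series`.
#' @export
mlats_series <- function(records, body_part = c("right_hand", "left_hand", "mouth"),
                         child_id = "child", palette = default_palette(),
                         strict = FALSE) {
  body_part <- match.arg(body_part)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  needed <- c("activity_type", "location", "object_surface", "duration_s")
  if (!all(needed %in% names(records))) {
    stop("records must have columns: ", paste(needed, collapse = ", "))
  }
  records <- records[, needed]
  if (nrow(records) > 0) {
    records$activity_type <- tolower(trimws(records$activity_type))
    records$location <- trimws(records$location)
    records$object_surface <- trimws(records$object_surface)
    records$duration_s <- as.numeric(records$duration_s)
    problems <- character(0)
    bad_type <- which(!records$activity_type %in% c("constant", "repetitive"))
    if (length(bad_type) > 0) {
      problems <- c(problems, paste0(
        "row ", bad_type, ": unknown activity type '",
        records$activity_type[bad_type], "'"
      ))
    }
    bad_dur <- which(!is.finite(records$duration_s) | records$duration_s <= 0)
    if (length(bad_dur) > 0) {
      problems <- c(problems, paste0(
        "row ", bad_dur, ": non-positive or missing duration"
      ))
    }
    empty_tok <- which(!nzchar(records$location) | !nzchar(records$object_surface))
    if (length(empty_tok) > 0) {
      problems <- c(problems, paste0("row ", empty_tok, ": empty token"))
    }
    if (length(problems) > 0) {
      stop("invalid MLATS records:\n  ", paste(problems, collapse = "\n  "))
    }
    unknown_loc <- setdiff(unique(records$location), palette$locations)
    unknown_obj <- setdiff(unique(records$object_surface), palette$objects)
    unknown <- c(
      if (length(unknown_loc)) paste0("location '", unknown_loc, "'"),
      if (length(unknown_obj)) paste0("object '", unknown_obj, "'")
    )
    if (length(unknown) > 0) {
      msg <- paste0(
        "tokens outside palette: ", paste(unknown, collapse = ", ")
      )
      if (strict) stop(msg) else warning(msg, call. = FALSE)
    }
  }
  structure(
    list(body_part = body_part, child_id = child_id, records = records),
    class = "mlats_series"
  )
}

#' @export
print.mlats_series <- function(x, ...) {
  cat(sprintf(
    "<mlats_series> %s, child '%s': %d records, %.0f s observed\n",
    x$body_part, x$child_id, nrow(x$records), total_duration(x)
  ))
  invisible(x)
}

#' Total observed duration of a series, in seconds
#' @param series An `mlats_series`.
#' @return Numeric scalar (seconds).
#' @export
total_duration <- function(series) {
  stopifnot(inherits(series, "mlats_series"))
  sum(series$records$duration_s)
}

# Canonicalize a header name: case-insensitive, punctuation-insensitive,
# so "Object/Surface", "Object_Surface" and "object surface" all match.
canon_header <- function(x) {
  x <- tolower(gsub("[^[:alnum:]]+", "", x))
  x
}

.mlats_header_map <- c(
  activitytype = "activity_type",
  location = "location",
  objectsurface = "object_surface",
  duration = "duration_s",
  durationseconds = "duration_s",
  durations = "duration_s"
)

#' Parse an MLATS text file
#'
#' Reads the tab-delimited text dialect produced by videotranslation software:
#' a header row naming the four columns (activity type, location,
#' object/surface, duration in seconds) followed by one row per sequential
#' activity record. Column names are matched case-insensitively after
#' stripping punctuation, so `Object/Surface` and `Object_Surface` are
#' equivalent. Runs of spaces are accepted as a field separator when the line
#' contains no tab. Trailing whitespace and blank lines are ignored. The body
#' part is supplied by the caller because the file format does not encode it.
#'
#' @param file Path to a file, or a character vector of lines, or a
#'   connection.
#' @param body_part One of `"right_hand"`, `"left_hand"`, `"mouth"`.
#' @param child_id Identifier recorded on the series.
#' @param palette Token vocabulary; see [default_palette()].
#' @param strict If `TRUE`, tokens outside the palette are an error.
#' @return An [mlats_series()].
#' @export
#' @examples
#' lines <- c(
#'   "Activity type\tLocation\tObject/Surface\tDuration (Seconds)",
#'   "Constant\tBedroom\tHard_Toy\t15",
#'   "Constant\tBedroom\tNothing\t5"
#' )
#' s <- parse_mlats(lines, body_part = "right_hand")
#' total_duration(s)
parse_mlats <- function(file, body_part = c("right_hand", "left_hand", "mouth"),
                        child_id = "child", palette = default_palette(),
                        strict = FALSE) {
  body_part <- match.arg(body_part)
  lines <- if (is.character(file) && length(file) > 1) {
    file
  } else if (is.character(file) && !file.exists(file) && grepl("[\t\n]", file)) {
    strsplit(file, "\n", fixed = TRUE)[[1]]
  } else {
    readLines(file, warn = FALSE)
  }
  lines <- sub("[ \t\r]+$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty MLATS input: no header row")

  split_fields <- function(line) {
    if (grepl("\t", line, fixed = TRUE)) {
      fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    } else {
      fields <- strsplit(line, " {2,}")[[1]]
    }
    trimws(fields)
  }

  header <- split_fields(lines[1])
  mapped <- .mlats_header_map[canon_header(header)]
  if (anyNA(mapped)) {
    stop(
      "unrecognized MLATS column header(s): ",
      paste(header[is.na(mapped)], collapse = ", ")
    )
  }
  needed <- c("activity_type", "location", "object_surface", "duration_s")
  if (!setequal(mapped, needed)) {
    stop(
      "MLATS header must name the four columns (activity type, location, ",
      "object/surface, duration); got: ", paste(header, collapse = ", ")
    )
  }

  body <- lines[-1]
  if (length(body) == 0) {
    records <- data.frame(
      activity_type = character(0), location = character(0),
      object_surface = character(0), duration_s = numeric(0),
      stringsAsFactors = FALSE
    )
    return(mlats_series(records, body_part, child_id, palette, strict))
  }
  parsed <- lapply(body, split_fields)
  nf <- lengths(parsed)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))
    stop(
      "malformed MLATS row(s) (wrong field count): row ",
      paste(bad, collapse = ", ")
    )
  }
  mat <- do.call(rbind, parsed)
  colnames(mat) <- mapped
  records <- data.frame(
    activity_type = unquote_token(mat[, "activity_type"]),
    location = unquote_token(mat[, "location"]),
    object_surface = unquote_token(mat[, "object_surface"]),
    duration_s = suppressWarnings(as.numeric(mat[, "duration_s"])),
    stringsAsFactors = FALSE
  )
  bad_dur <- which(is.na(records$duration_s))
  if (length(bad_dur) > 0) {
    stop("non-numeric duration at row ", paste(bad_dur, collapse = ", "))
  }
  mlats_series(records, body_part, child_id, palette, strict)
}

# Tokens containing whitespace are written double-quoted; strip on read.
unquote_token <- function(x) {
  q <- grepl('^".*"$', x)
  x[q] <- substr(x[q], 2, nchar(x[q]) - 1)
  x
}

quote_token <- function(x) {
  needs <- grepl("[[:space:]]", x)
  x[needs] <- paste0('"', x[needs], '"')
  x
}

#' Write an MLATS series as text
#'
#' Emits the tab-delimited dialect read by [parse_mlats()]; the round trip
#' `parse_mlats(write_mlats(s))` reproduces `s` exactly. Tokens containing
#' whitespace are double-quoted.
#'
#' @param series An [mlats_series()].
#' @param file Optional path; when `NULL` the lines are returned invisibly
#'   only.
#' @return Character vector of lines, invisibly.
#' @export
write_mlats <- function(series, file = NULL) {
  stopifnot(inherits(series, "mlats_series"))
  r <- series$records
  header <- "Activity type\tLocation\tObject/Surface\tDuration (Seconds)"
  if (nrow(r) == 0) {
    lines <- header
  } else {
    act <- paste0(
      toupper(substr(r$activity_type, 1, 1)), substr(r$activity_type, 2, nchar(r$activity_type))
    )
    lines <- c(header, paste(
      act, quote_token(r$location), quote_token(r$object_surface),
      vapply(r$duration_s, function(d) sprintf("%.15g", d), ""),
      sep = "\t"
    ))
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Convert an MLATS series to timed contact events
#'
#' Event k covers `[start_s, end_s)` where `start_s` is the cumulative sum of
#' the durations of records 1..k-1; events tile the observation window with
#' no gaps. Repetitive records are annotated with a sub-contact count at
#' `sub_contact_rate` contacts per second (minimum 1); constant records count
#' as a single contact at record start.
#'
#' @param series An [mlats_series()].
#' @param sub_contact_rate Sub-contacts per second for repetitive records.
#' @return A data frame with columns `start_s`, `end_s`, `activity_type`,
#'   `location`, `object_surface`, `duration_s`, `sub_contact_count`.
#' @export
series_to_events <- function(series, sub_contact_rate = 0.5) {
  stopifnot(inherits(series, "mlats_series"), sub_contact_rate > 0)
  r <- series$records
  if (nrow(r) == 0) {
    return(data.frame(
      start_s = numeric(0), end_s = numeric(0), activity_type = character(0),
      location = character(0), object_surface = character(0),
      duration_s = numeric(0), sub_contact_count = integer(0),
      stringsAsFactors = FALSE
    ))
  }
  ends <- cumsum(r$duration_s)
  starts <- c(0, ends[-length(ends)])
  nsub <- ifelse(
    r$activity_type == "repetitive",
    pmax(1L, as.integer(round(r$duration_s * sub_contact_rate))),
    1L
  )
  data.frame(
    start_s = starts, end_s = ends,
    activity_type = r$activity_type, location = r$location,
    object_surface = r$object_surface, duration_s = r$duration_s,
    sub_contact_count = nsub, stringsAsFactors = FALSE
  )
}

#' Summarize contact frequency and duration by category
#'
#' Contacts are counted as maximal runs of a category: consecutive records
#' with the same grouping value merge into one contact, and a return to a
#' category after an interruption starts a new contact. This matches how
#' videotranslators emit a new row per palette change. Raw row counts are
#' also reported. `Not_In_View` intervals are excluded from the contact-count
#' numerator but contribute elapsed time (unless `drop_not_in_view_time`).
#'
#' @param series An [mlats_series()].
#' @param group_by One of `"object"`, `"location"`, `"activity_type"`.
#' @param palette Palette supplying the reserved tokens.
#' @param drop_not_in_view_time If `TRUE`, `Not_In_View` time is removed from
#'   the denominator used for frequencies and time fractions.
#' @return A list of class `contact_summary` with a `table` data frame
#'   (category, n_contacts, n_rows, total_s, frequency_per_h, time_fraction)
#'   plus `observed_s` and `group_by`.
#' @export
summarize_contacts <- function(series,
                               group_by = c("object", "location", "activity_type"),
                               palette = default_palette(),
                               drop_not_in_view_time = FALSE) {
  stopifnot(inherits(series, "mlats_series"))
  group_by <- match.arg(group_by)
  r <- series$records
  key <- switch(group_by,
    object = r$object_surface,
    location = r$location,
    activity_type = r$activity_type
  )
  observed <- sum(r$duration_s)
  niv <- palette$not_in_view_token
  denom_s <- observed
  if (drop_not_in_view_time && nrow(r) > 0) {
    denom_s <- observed - sum(r$duration_s[r$object_surface == niv])
  }
  if (nrow(r) == 0) {
    tab <- data.frame(
      category = character(0), n_contacts = integer(0), n_rows = integer(0),
      total_s = numeric(0), frequency_per_h = numeric(0),
      time_fraction = numeric(0), stringsAsFactors = FALSE
    )
    return(structure(
      list(table = tab, observed_s = 0, group_by = group_by),
      class = "contact_summary"
    ))
  }
  runs <- rle(key)
  n_contacts <- tapply(rep(1L, length(runs$values)), runs$values, sum)
  n_rows <- tapply(rep(1L, nrow(r)), key, sum)
  total_s <- tapply(r$duration_s, key, sum)
  cats <- sort(unique(key))
  freq <- if (denom_s > 0) {
    as.numeric(n_contacts[cats]) / (denom_s / 3600)
  } else {
    rep(NA_real_, length(cats))
  }
  freq[cats == niv] <- if (denom_s > 0) 0 else NA_real_
  tab <- data.frame(
    category = cats,
    n_contacts = as.integer(n_contacts[cats]),
    n_rows = as.integer(n_rows[cats]),
    total_s = as.numeric(total_s[cats]),
    frequency_per_h = freq,
    time_fraction = as.numeric(total_s[cats]) / denom_s,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(
    list(table = tab, observed_s = observed, group_by = group_by),
    class = "contact_summary"
  )
}

#' @export
print.contact_summary <- function(x, ...) {
  cat(sprintf(
    "<contact_summary> by %s over %.0f s observed\n", x$group_by, x$observed_s
  ))
  print(x$table, ...)
  invisible(x)
}

#' Contact frequency with objects, excluding non-contact tokens
#'
#' Convenience wrapper: contacts per hour counting only real object/surface
#' contacts (excluding `Nothing` and `Not_In_View`).
#'
#' @inheritParams summarize_contacts
#' @return Contacts per hour (numeric scalar). Errors on a zero-duration
#'   series.
#' @export
object_contact_frequency <- function(series, palette = default_palette()) {
  if (total_duration(series) <= 0) {
    stop("contact frequency undefined for a zero-duration series")
  }
  s <- summarize_contacts(series, "object", palette)
  tab <- s$table
  skip <- c(palette$no_contact_token, palette$not_in_view_token)
  sum(tab$n_contacts[!tab$category %in% skip]) / (s$observed_s / 3600)
}
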