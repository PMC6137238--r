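#' Read a cohort table
#'
#' The cohort table is tab-delimited long format: one row per (participant,
#' alter) placement with participant fields repeated. Required columns:
#' `participant_id`, `severity_response`, `alter_label`, `circle`, and either
#' `rqlq_items` (semicolon-separated item scores) or `rqlq_mean`. Optional:
#' `age`, `sex`, `region`. Participants appear in interview order (order of
#' first appearance). Validation failures report the offending row number.
#'
#' @param path Path to the TSV file.
#' @param taxonomy An [alter_taxonomy()].
#' @param qol_breaks Passed to [bin_qol()].
#' @param n_circles Number of circles (default 4).
#' @return An `ar_cohort`.
#' @export
read_cohort_table <- function(path, taxonomy = alter_taxonomy(),
                              qol_breaks = c(2, 4), n_circles = 4) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cohort_from_table(df, taxonomy = taxonomy, qol_breaks = qol_breaks,
                    n_circles = n_circles)
}

#' Validate an in-memory cohort table
#'
#' Same contract as [read_cohort_table()] but starting from a data.frame, as
#' produced by [generate_cohort()].
#'
#' @param df Long-format cohort data.frame.
#' @inheritParams read_cohort_table
#' @return An `ar_cohort`.
#' @export
cohort_from_table <- function(df, taxonomy = alter_taxonomy(),
                              qol_breaks = c(2, 4), n_circles = 4) {
  required <- c("participant_id", "severity_response", "alter_label", "circle")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("cohort table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  has_items <- "rqlq_items" %in% names(df)
  if (!has_items && !("rqlq_mean" %in% names(df))) {
    stop("cohort table needs either an rqlq_items or an rqlq_mean column",
         call. = FALSE)
  }
  bad_circle <- which(is.na(df$circle) | df$circle != trunc(df$circle) |
                        df$circle < 1 | df$circle > n_circles)
  if (length(bad_circle)) {
    stop("invalid circle value at row(s): ",
         paste(utils::head(bad_circle, 5), collapse = ", "),
         " (must be an integer in 1..", n_circles, ")", call. = FALSE)
  }
  ids <- unique(df$participant_id)  # first-appearance = interview order
  groups <- split(seq_len(nrow(df)),
                  factor(df$participant_id, levels = ids))
  egos <- lapply(ids, function(pid) {
    rows <- df[groups[[pid]], , drop = FALSE]
    first <- rows[1, ]
    rqlq <- if (has_items && !is.na(first$rqlq_items) &&
                nzchar(first$rqlq_items)) {
      as.numeric(strsplit(as.character(first$rqlq_items), ";",
                          fixed = TRUE)[[1]])
    } else {
      NULL
    }
    tryCatch(
      build_ego_network(
        id = pid,
        severity_response = first$severity_response,
        rqlq = if (is.null(rqlq)) first$rqlq_mean else rqlq,
        rqlq_is_mean = is.null(rqlq),
        alters = rows$alter_label,
        circles = rows$circle,
        age = if ("age" %in% names(rows)) first$age else NA,
        sex = if ("sex" %in% names(rows)) first$sex else NA,
        region = if ("region" %in% names(rows)) first$region else NA,
        taxonomy = taxonomy, qol_breaks = qol_breaks, n_circles = n_circles
      ),
      error = function(e) {
        stop("participant ", pid, " (first at row ",
             which(df$participant_id == pid)[1], "): ", conditionMessage(e),
             call. = FALSE)
      }
    )
  })
  as_ar_cohort(egos)
}

#' Write a cohort table
#'
#' Inverse of [read_cohort_table()]: writes the validated cohort back to the
#' long-format TSV dialect (canonical alter codes, items rejoined with `;`).
#' Reading the written file reproduces the cohort exactly.
#'
#' @param cohort An `ar_cohort` or `ar_cohort_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  cohort <- as_ar_cohort(cohort)
  rows <- lapply(cohort, function(p) {
    data.frame(
      participant_id = p$id, age = p$age, sex = p$sex, region = p$region,
      severity_response = severity_responses()$response[
        match(p$severity, severity_responses()$code)],
      rqlq_items = if (is.null(p$rqlq$items)) "" else
        paste(format(p$rqlq$items, trim = TRUE, scientific = FALSE),
              collapse = ";"),
      rqlq_mean = p$rqlq$mean_score,
      alter_label = p$placements$alter,
      circle = p$placements$circle,
      stringsAsFactors = FALSE
    )
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

circle_to_strength <- function(circle, n_circles = 4) {
  as.integer(n_circles) + 1L - as.integer(circle)
}

# quote labels containing whitespace, VNA-style
vna_quote <- function(x) ifelse(grepl("\\s", x), paste0('"', x, '"'), x)

#' Write a NetDraw-compatible VNA file
#'
#' Encodes a cohort network in the plain-text VNA dialect understood by
#' NetDraw: a `*node data` section (`ID label group value`, space-delimited,
#' labels quoted when they contain spaces) followed by a `*tie data` section
#' (`from to strength`). Tie strength is the circle weight: circle 1 (most
#' influential) maps to strength 4, circle 4 to strength 1.
#'
#' In `aggregate` mode one document holds every ego, every alter (node value =
#' placement-weighted mean circle weight) and one tie per (ego, alter)
#' placement. In `per-ego` mode `path` is a directory and one `<id>.vna`
#' document is written per ego with node value = that ego's circle weight.
#'
#' @param cohort An `ar_cohort_network`.
#' @param path Output file (aggregate mode) or directory (per-ego mode).
#' @param mode `"aggregate"` or `"per-ego"`.
#' @param taxonomy Taxonomy used for node labels and groups.
#' @return The path(s) written, invisibly.
#' @export
write_vna <- function(cohort, path, mode = c("aggregate", "per-ego"),
                      taxonomy = alter_taxonomy()) {
  stopifnot(inherits(cohort, "ar_cohort_network"))
  mode <- match.arg(mode)
  nc <- cohort$n_circles
  if (mode == "per-ego") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    paths <- vapply(cohort$egos, function(p) {
      f <- file.path(path, paste0(p$id, ".vna"))
      one <- aggregate_cohort(list(p), n_circles = nc)
      write_vna_one(one, f, taxonomy)
      f
    }, character(1))
    return(invisible(paths))
  }
  write_vna_one(cohort, path, taxonomy)
  invisible(path)
}

write_vna_one <- function(cohort, path, taxonomy) {
  nc <- cohort$n_circles
  pl <- cohort_placements(cohort)
  if (is.null(pl) || nrow(pl) == 0) stop("network has no placements",
                                         call. = FALSE)
  strength <- circle_to_strength(pl$circle, nc)
  # per-alter value: placement-weighted mean circle weight
  val <- tapply(strength, pl$alter, mean)
  alters <- sort(unique(pl$alter))
  lbl <- taxonomy$display_name[match(alters, taxonomy$code)]
  lbl[is.na(lbl)] <- alters[is.na(lbl)]
  grp <- taxonomy$group[match(alters, taxonomy$code)]
  grp[is.na(grp)] <- "unknown"
  egos <- vapply(cohort$egos, function(p) p$id, character(1))
  lines <- c(
    "*node data",
    "ID label group value",
    paste(vna_quote(egos), vna_quote(egos), "ego", 0),
    paste(vna_quote(alters), vna_quote(lbl), vna_quote(grp),
          format(as.numeric(val[alters]), trim = TRUE, scientific = FALSE)),
    "*tie data",
    "from to strength",
    paste(vna_quote(pl$ego), vna_quote(pl$alter), strength)
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a VNA file back into placements
#'
#' Inverse of [write_vna()]: parses the node and tie sections and maps tie
#' strengths back onto circles (`strength s` -> `circle n_circles + 1 - s`).
#' Rejects unknown section headers, strengths outside `1:n_circles`, ties that
#' reference undeclared nodes, and documents with no ties.
#'
#' @param path Path to a VNA file.
#' @param n_circles Number of circles (default 4).
#' @return data.frame `ego`, `alter`, `circle`, one row per placement, in file
#'   order.
#' @export
read_vna <- function(path, n_circles = 4) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sec <- grep("^\\*", lines)
  headers <- tolower(trimws(lines[sec]))
  known <- c("*node data", "*tie data")
  if (!all(headers %in% known) || !("*tie data" %in% headers)) {
    stop("unknown or missing VNA section header(s): expected ",
         paste(known, collapse = " and "), call. = FALSE)
  }
  # tokenizer honouring quoted labels
  toks <- function(line) scan(text = line, what = character(), quiet = TRUE)
  section_rows <- function(name) {
    i <- sec[headers == name]
    if (!length(i)) return(NULL)
    end <- c(sec[-1] - 1, length(lines))[match(i, sec)]
    if (end < i + 2) return(list())  # header + column line only: no rows
    body <- lines[seq(i + 2, end)]   # skip the column header line
    lapply(body, toks)
  }
  nodes <- section_rows("*node data")
  node_ids <- vapply(nodes, `[`, character(1), 1)
  ties <- section_rows("*tie data")
  if (length(ties) == 0) stop("VNA tie section is empty: a network must have ",
                              "at least one tie", call. = FALSE)
  from <- vapply(ties, `[`, character(1), 1)
  to <- vapply(ties, `[`, character(1), 2)
  strength <- as.integer(vapply(ties, `[`, character(1), 3))
  if (anyNA(strength) || any(strength < 1 | strength > n_circles)) {
    stop("tie strength must be an integer in 1..", n_circles, call. = FALSE)
  }
  if (length(node_ids) && !all(c(from, to) %in% node_ids)) {
    stop("tie references undeclared node(s): ",
         paste(unique(setdiff(c(from, to), node_ids)), collapse = ", "),
         call. = FALSE)
  }
  data.frame(ego = from, alter = to,
             circle = circle_to_strength(strength, n_circles),
             stringsAsFactors = FALSE)
}
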