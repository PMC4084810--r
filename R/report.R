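# Tabular reports: a CSV with one row per node, and an HTML table with
# nodes as columns and time steps as rows. Community colours are assigned
# deterministically from the community id so reruns produce identical
# reports.

.palette <- c("#e6194b", "#3cb44b", "#ffe119", "#4363d8", "#f58231",
              "#911eb4", "#46f0f0", "#f032e6", "#bcf60c", "#fabebe",
              "#008080", "#e6beff", "#9a6324", "#fffac8", "#800000",
              "#aaffc3", "#808000", "#ffd8b1", "#000075", "#808080")

#' Deterministic colour for a community id
#' @param id positive integer community (or sub-community) id
#' @return hex colour string
#' @export
community_colour <- function(id) .palette[(as.integer(id) - 1L) %%
                                            length(.palette) + 1L]

.absence_marker <- "-"

.membership_df <- function(memb) {
  df <- as.data.frame(ifelse(is.na(memb), .absence_marker,
                             as.character(memb)),
                      stringsAsFactors = FALSE)
  names(df) <- paste0("t_", colnames(memb))
  df
}

#' Write a per-node membership table as CSV
#'
#' One row per node. The first column is the node id; the next T columns
#' (\code{t_<time>}) give the community of the node's group at each time,
#' with the literal marker \code{-} where the node is absent. For a
#' cost-model result these are followed by \code{home_<time>} columns and
#' the itemised per-node costs (\code{n_switch}, \code{n_visit},
#' \code{n_absence}, \code{cost}); for a sub-community result by
#' \code{label} (\code{-} when unassigned), \code{original_community} and
#' \code{promiscuity}. The file is RFC 4180 CSV (UTF-8, CRLF, header row)
#' and is byte-identical across reruns on identical input.
#'
#' @param result a \code{home_assignment} or \code{subcommunity_assignment}
#' @param path output file path
#' @return invisibly, the data frame written
#' @export
write_membership_csv <- function(result, path) {
  df <- membership_table(result)
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, eol = "\r\n", quote = TRUE)
  invisible(df)
}

#' Per-node membership table as a data frame
#'
#' The data frame behind \code{\link{write_membership_csv}}; see there for
#' the column layout.
#' @param result a \code{home_assignment} or \code{subcommunity_assignment}
#' @return a data.frame, one row per node
#' @export
membership_table <- function(result) {
  if (inherits(result, "home_assignment")) {
    memb <- result$membership
    df <- cbind(data.frame(node = rownames(memb), stringsAsFactors = FALSE),
                .membership_df(memb))
    home_df <- as.data.frame(matrix(as.character(result$home),
                                    nrow = nrow(result$home)),
                             stringsAsFactors = FALSE)
    names(home_df) <- paste0("home_", colnames(memb))
    counts <- function(tag) apply(result$events, 1, function(r)
      sum(vapply(strsplit(r, "+", fixed = TRUE),
                 function(x) tag %in% x, logical(1))))
    cbind(df, home_df,
          data.frame(n_switch = counts("switch"), n_visit = counts("visit"),
                     n_absence = counts("absence"),
                     cost = unname(result$node_cost)))
  } else if (inherits(result, "subcommunity_assignment")) {
    memb <- result$pattern
    df <- cbind(data.frame(node = rownames(memb), stringsAsFactors = FALSE),
                .membership_df(memb))
    cbind(df, data.frame(
      label = ifelse(is.na(result$label), .absence_marker,
                     as.character(result$label)),
      original_community = unname(result$original),
      promiscuity = unname(result$promiscuity)))
  } else stop("'result' must be a home_assignment or subcommunity_assignment")
}

.html_box <- function(text, colour = NULL) {
  style <- if (is.null(colour)) "" else
    sprintf(" style=\"background:%s\"", colour)
  sprintf("<span class=\"box\"%s>%s</span>", style, text)
}

#' Write an HTML report of the community structure over time
#'
#' Renders the membership table with nodes as columns and time steps as
#' rows; every community is shown with a deterministic colour and its
#' number. For a cost-model result each cell holds two boxes: the left box
#' is the node's home community and the right box the community it actually
#' participates in at that time (shown only when it differs, i.e. a visit).
#' An absent node is shown as a dash; the dash keeps the home colour when
#' the home community is itself absent (no absence cost is incurred then,
#' since a node cannot attend a community that is not there). A
#' sub-community report adds a sub-community row, an original-community row
#' and a bottom row of per-column member counts, with a dash for nodes
#' whose unique pattern left them unassigned.
#'
#' @param result a \code{home_assignment} or \code{subcommunity_assignment}
#' @param network the \code{dynamic_network} the result was computed from
#'   (used for node and time ordering); may be NULL
#' @param path output file path
#' @return invisibly, \code{path}
#' @export
write_html_report <- function(result, network = NULL, path) {
  memb <- if (inherits(result, "home_assignment")) result$membership
          else result$pattern
  nodes <- rownames(memb)
  times <- colnames(memb)
  cell <- function(txt) paste0("<td>", txt, "</td>")
  rows <- character(0)
  header <- paste0("<tr><th></th>",
                   paste0("<th>", nodes, "</th>", collapse = ""), "</tr>")
  if (inherits(result, "subcommunity_assignment")) {
    lab <- result$label
    lab_cells <- vapply(seq_along(nodes), function(i) {
      if (is.na(lab[i])) cell(.absence_marker)
      else cell(.html_box(lab[i], community_colour(lab[i])))
    }, character(1))
    rows <- c(rows, paste0("<tr><th>sub-community</th>",
                           paste(lab_cells, collapse = ""), "</tr>"))
    orig_cells <- vapply(result$original, function(o)
      cell(.html_box(o, community_colour(o))), character(1))
    rows <- c(rows, paste0("<tr><th>original community</th>",
                           paste(orig_cells, collapse = ""), "</tr>"))
  }
  for (t in seq_along(times)) {
    cells <- vapply(seq_along(nodes), function(i) {
      m <- memb[i, t]
      if (inherits(result, "home_assignment")) {
        h <- result$home[i, t]
        left <- .html_box(h, community_colour(h))
        right <- if (!is.na(m)) {
          if (m != h) .html_box(m, community_colour(m)) else ""
        } else {
          ev <- result$events[i, t]
          if (grepl("exempt-absence", ev, fixed = TRUE))
            .html_box(.absence_marker, community_colour(h))
          else .html_box(.absence_marker)
        }
        cell(paste0(left, right))
      } else {
        if (is.na(m)) cell(.html_box(.absence_marker))
        else cell(.html_box(m, community_colour(m)))
      }
    }, character(1))
    rows <- c(rows, paste0("<tr><th>t=", times[t], "</th>",
                           paste(cells, collapse = ""), "</tr>"))
  }
  if (inherits(result, "subcommunity_assignment")) {
    sz <- vapply(seq_along(nodes), function(i) {
      l <- result$label[i]
      if (is.na(l)) .absence_marker
      else as.character(result$sizes[[as.character(l)]])
    }, character(1))
    rows <- c(rows, paste0("<tr><th>members</th>",
                           paste(vapply(sz, cell, character(1)),
                                 collapse = ""), "</tr>"))
  }
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\">",
    "<title>Dynamic community structure</title>",
    "<style>",
    "table{border-collapse:collapse;font-family:sans-serif;font-size:12px}",
    "td,th{border:1px solid #ccc;padding:2px 4px;text-align:center}",
    ".box{display:inline-block;min-width:1.6em;padding:1px 3px;margin:0 1px}",
    "</style></head><body>",
    "<table>", header, rows, "</table>",
    "</body></html>")
  writeLines(html, path, useBytes = TRUE)
  invisible(path)
}
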