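#' Assemble member models into a compartmentalized community model
#'
#' Integrates member genome-scale models into one stoichiometric matrix,
#' assigning each member's metabolites and reactions to its own namespace
#' (`member::id`) while merging extracellular species (identified by
#' compartment tag) into single shared rows. Reactions that touch only
#' extracellular species are community-level exchanges and are deduplicated
#' to one per original id.
#'
#' @param members List of `member_model` objects (see [read_member_sbml()]).
#' @param extracellular Compartment tag marking extracellular species.
#' @return A `community_model`: list with `members`, sparse matrix `S`
#'   (rownames are namespaced metabolite ids, extracellular species keep their
#'   original id), `rxns` (tibble: `col`, `member`, `orig_id`, `direction`,
#'   `lb`, `ub`, `gpr_key`), `mets` (tibble: `row`, `scope`, `orig_id`),
#'   named vector `biomass` (member -> column), named list `gpr` keyed by
#'   `gpr_key`, and flag `irreversible` (`FALSE` here; see
#'   [to_irreversible()]).
#' @export
build_community <- function(members, extracellular = "e") {
  stopifnot(is.list(members), length(members) >= 1L)
  stopifnot(all(vapply(members, inherits, logical(1), "member_model")))
  ids <- vapply(members, `[[`, character(1), "member_id")
  if (anyDuplicated(ids)) {
    stop("duplicate member_id: ", paste(ids[duplicated(ids)], collapse = ", "), call. = FALSE)
  }

  rows <- character(0); row_scope <- character(0); row_orig <- character(0)
  cols <- character(0); col_member <- col_orig <- col_gpr <- character(0)
  col_lb <- col_ub <- numeric(0)
  trip_i <- trip_j <- integer(0); trip_x <- numeric(0)
  gpr_map <- list(); biomass <- character(0)
  ex_seen <- character(0)

  add_row <- function(id, scope, orig) {
    rows <<- c(rows, id); row_scope <<- c(row_scope, scope); row_orig <<- c(row_orig, orig)
    length(rows)
  }

  for (m in members) {
    is_ext <- m$mets$compartment == extracellular
    row_of <- integer(nrow(m$mets))
    for (k in seq_len(nrow(m$mets))) {
      if (is_ext[k]) {
        hit <- match(m$mets$id[k], rows)
        row_of[k] <- if (is.na(hit)) add_row(m$mets$id[k], "extracellular", m$mets$id[k]) else hit
      } else {
        row_of[k] <- add_row(paste0(m$member_id, "::", m$mets$id[k]), m$member_id, m$mets$id[k])
      }
    }
    Sm <- m$S
    for (k in seq_len(nrow(m$rxns))) {
      rid <- m$rxns$id[k]
      nz <- which(Sm[, k] != 0)
      exchange <- length(nz) > 0L && all(is_ext[nz])
      if (exchange) {
        if (rid %in% ex_seen) {
          j <- match(rid, col_orig[col_member == "community"])
          jj <- which(col_member == "community")[j]
          if (abs(col_lb[jj] - m$rxns$lb[k]) > 1e-12 || abs(col_ub[jj] - m$rxns$ub[k]) > 1e-12) {
            warning("exchange reaction ", rid, " has conflicting bounds across members; ",
                    "keeping the union")
            col_lb[jj] <- min(col_lb[jj], m$rxns$lb[k])
            col_ub[jj] <- max(col_ub[jj], m$rxns$ub[k])
          }
          next
        }
        ex_seen <- c(ex_seen, rid)
        cols <- c(cols, rid); col_member <- c(col_member, "community")
        col_orig <- c(col_orig, rid); col_gpr <- c(col_gpr, NA_character_)
        col_lb <- c(col_lb, m$rxns$lb[k]); col_ub <- c(col_ub, m$rxns$ub[k])
      } else {
        key <- paste0(m$member_id, "::", rid)
        cols <- c(cols, key); col_member <- c(col_member, m$member_id)
        col_orig <- c(col_orig, rid)
        has_gpr <- !is.null(m$gpr[[rid]])
        col_gpr <- c(col_gpr, if (has_gpr) key else NA_character_)
        if (has_gpr) gpr_map[[key]] <- m$gpr[[rid]]
        col_lb <- c(col_lb, m$rxns$lb[k]); col_ub <- c(col_ub, m$rxns$ub[k])
        if (rid == m$biomass_reaction_id) biomass[m$member_id] <- key
      }
      j <- length(cols)
      trip_i <- c(trip_i, row_of[nz]); trip_j <- c(trip_j, rep(j, length(nz)))
      trip_x <- c(trip_x, Sm[nz, k])
    }
    if (!m$member_id %in% names(biomass)) {
      stop("biomass reaction of member ", m$member_id,
           " resolved to a community exchange; check the model", call. = FALSE)
    }
  }

  S <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(length(rows), length(cols)),
                            dimnames = list(rows, cols))
  structure(list(
    members = ids,
    S = S,
    rxns = tibble::tibble(col = cols, member = col_member, orig_id = col_orig,
                          direction = "single", lb = col_lb, ub = col_ub,
                          gpr_key = col_gpr),
    mets = tibble::tibble(row = rows, scope = row_scope, orig_id = row_orig),
    biomass = biomass,
    gpr = gpr_map,
    irreversible = FALSE
  ), class = "community_model")
}

#' Convert a community model to nonnegative-flux (irreversible) form
#'
#' Splits every reversible reaction (negative lower bound) into forward and
#' reverse columns with bounds `(0, ub)` and `(0, -lb)`; both columns inherit
#' the reaction's GPR. Net flux is recoverable as forward minus reverse (see
#' [net_fluxes()]). Reactions with a strictly positive lower bound are kept as
#' is with a warning (the forced flux is preserved as a constraint by the
#' solver).
#'
#' @param model A `community_model` from [build_community()].
#' @return The model with `irreversible = TRUE` and all lower bounds
#'   nonnegative (except warned forced-flux reactions).
#' @export
to_irreversible <- function(model) {
  stopifnot(inherits(model, "community_model"))
  if (isTRUE(model$irreversible)) return(model)
  if (any(model$rxns$lb > model$rxns$ub)) {
    stop("reaction with lower bound > upper bound", call. = FALSE)
  }
  forced <- model$rxns$lb > 0
  if (any(forced)) {
    warning("forced-flux reaction(s) kept with positive lower bound: ",
            paste(model$rxns$col[forced], collapse = ", "))
  }
  S_new <- list(); rx <- list()
  for (k in seq_len(nrow(model$rxns))) {
    r <- model$rxns[k, ]
    colvec <- model$S[, k, drop = FALSE]
    if (r$lb < 0 && r$ub > 0) {
      fwd <- r; fwd$lb <- 0; fwd$direction <- "fwd"
      rev <- r; rev$col <- paste0(r$col, "__rev"); rev$lb <- 0; rev$ub <- -r$lb
      rev$direction <- "rev"
      S_new <- c(S_new, list(colvec, -colvec))
      rx <- c(rx, list(fwd, rev))
    } else if (r$lb < 0 && r$ub <= 0) {
      # runs only backwards: represent as a single reverse column
      rev <- r; rev$col <- paste0(r$col, "__rev"); rev$lb <- if (r$ub < 0) -r$ub else 0
      rev$ub <- -r$lb; rev$direction <- "rev"
      S_new <- c(S_new, list(-colvec)); rx <- c(rx, list(rev))
    } else {
      S_new <- c(S_new, list(colvec)); rx <- c(rx, list(r))
    }
  }
  rxns <- dplyr::bind_rows(rx)
  S <- do.call(cbind, S_new)
  colnames(S) <- rxns$col
  model$S <- S
  model$rxns <- rxns
  model$irreversible <- TRUE
  model
}

#' Net fluxes from an irreversible-model flux vector
#'
#' Collapses forward/reverse split columns back to signed net flux per
#' original reaction.
#'
#' @param model A `community_model` in irreversible form.
#' @param v Named numeric flux vector over the model's columns.
#' @return Tibble with `member`, `orig_id`, `net_flux`.
#' @export
net_fluxes <- function(model, v) {
  stopifnot(inherits(model, "community_model"), isTRUE(model$irreversible))
  x <- model$rxns
  x$flux <- as.numeric(v[x$col])
  x$signed <- ifelse(x$direction == "rev", -x$flux, x$flux)
  dplyr::summarise(dplyr::group_by(x, .data$member, .data$orig_id),
                   net_flux = sum(.data$signed), .groups = "drop")
}

#' Override exchange-reaction uptake bounds (growth medium)
#'
#' Exchange reactions follow the convention `species -> (environment)`, so
#' uptake is flux in the reverse direction. On a reversible model this sets
#' the exchange lower bound to `-max_uptake`; on an irreversible model it sets
#' the upper bound of the reverse column.
#'
#' @param model A `community_model`.
#' @param medium Data frame with columns `exchange_reaction_id`, `max_uptake`.
#' @return The modified model.
#' @export
apply_medium <- function(model, medium) {
  stopifnot(inherits(model, "community_model"))
  stopifnot(all(c("exchange_reaction_id", "max_uptake") %in% names(medium)))
  for (k in seq_len(nrow(medium))) {
    rid <- medium$exchange_reaction_id[k]
    up <- medium$max_uptake[k]
    if (isTRUE(model$irreversible)) {
      j <- which(model$rxns$orig_id == rid & model$rxns$member == "community" &
                   model$rxns$direction == "rev")
      if (length(j) == 0L) {
        warning("no reverse (uptake) column for exchange reaction ", rid); next
      }
      model$rxns$ub[j] <- up
    } else {
      j <- which(model$rxns$orig_id == rid & model$rxns$member == "community")
      if (length(j) == 0L) {
        warning("unknown exchange reaction ", rid); next
      }
      model$rxns$lb[j] <- -up
    }
  }
  model
}

#' @export
print.community_model <- function(x, ...) {
  cat("<community_model> ", length(x$members), " member(s): ",
      paste(x$members, collapse = ", "), "\n  ",
      nrow(x$mets), " metabolites (",
      sum(x$mets$scope == "extracellular"), " extracellular), ",
      nrow(x$rxns), " reaction columns (", length(x$gpr), " GPR rules), ",
      if (isTRUE(x$irreversible)) "irreversible" else "reversible", " form\n", sep = "")
  invisible(x)
}

#' Export a community model as plain tables
#'
#' @param model A `community_model`.
#' @return List of tibbles: `reactions`, `metabolites`, `stoichiometry`
#'   (sparse triplets), and `info` (members, biomass columns, form).
#' @export
community_tables <- function(model) {
  stopifnot(inherits(model, "community_model"))
  tr <- Matrix::summary(model$S)
  rxns <- model$rxns
  rxns$gpr <- vapply(rxns$gpr_key, function(k) {
    if (is.na(k) || is.null(model$gpr[[k]])) NA_character_ else deparse_gpr(model$gpr[[k]])
  }, character(1))
  list(
    reactions = rxns,
    metabolites = model$mets,
    stoichiometry = tibble::tibble(row = model$mets$row[tr$i],
                                   col = model$rxns$col[tr$j], value = tr$x),
    info = tibble::tibble(
      key = c("irreversible", paste0("biomass::", names(model$biomass))),
      value = c(as.character(model$irreversible), unname(model$biomass))
    )
  )
}

#' Write / read a community model bundle (tab-separated tables)
#'
#' The bundle is a directory of four TSV files mirroring
#' [community_tables()]; [read_community_bundle()] reconstructs the model,
#' including GPR trees, exactly.
#'
#' @param model A `community_model`.
#' @param dir Directory to create/write into.
#' @return `dir` (write) or a `community_model` (read), invisibly for write.
#' @export
write_community_bundle <- function(model, dir) {
  tabs <- community_tables(model)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tabs)) {
    readr::write_tsv(tabs[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  invisible(dir)
}

#' @rdname write_community_bundle
#' @export
read_community_bundle <- function(dir) {
  rd <- function(nm) readr::read_tsv(file.path(dir, paste0(nm, ".tsv")),
                                     show_col_types = FALSE)
  rxns <- rd("reactions"); mets <- rd("metabolites")
  trip <- rd("stoichiometry"); info <- rd("info")
  S <- Matrix::sparseMatrix(i = match(trip$row, mets$row),
                            j = match(trip$col, rxns$col), x = trip$value,
                            dims = c(nrow(mets), nrow(rxns)),
                            dimnames = list(mets$row, rxns$col))
  gpr <- list()
  for (k in which(!is.na(rxns$gpr))) {
    if (!is.na(rxns$gpr_key[k]) && is.null(gpr[[rxns$gpr_key[k]]])) {
      gpr[[rxns$gpr_key[k]]] <- parse_gpr(rxns$gpr[k])
    }
  }
  bio <- info[startsWith(info$key, "biomass::"), ]
  structure(list(
    members = unique(bio$key) |> sub(pattern = "^biomass::", replacement = ""),
    S = S,
    rxns = rxns[setdiff(names(rxns), "gpr")],
    mets = mets,
    biomass = stats::setNames(bio$value, sub("^biomass::", "", bio$key)),
    gpr = gpr,
    irreversible = as.logical(info$value[info$key == "irreversible"])
  ), class = "community_model")
}

#' Write a community model to a single SBML file
#'
#' Each member becomes a compartment; extracellular species live in
#' compartment `"e"`. Namespaced ids are preserved so the file documents the
#' assembled model rather than the original member files.
#'
#' @param model A `community_model`.
#' @param path Output path.
#' @export
write_community_sbml <- function(model, path) {
  stopifnot(inherits(model, "community_model"))
  comp <- ifelse(model$mets$scope == "extracellular", "e",
                 gsub("[^A-Za-z0-9_]", "_", model$mets$scope))
  gpr <- list()
  for (k in seq_len(nrow(model$rxns))) {
    key <- model$rxns$gpr_key[k]
    if (!is.na(key) && !is.null(model$gpr[[key]])) gpr[[model$rxns$col[k]]] <- model$gpr[[key]]
  }
  adapter <- structure(list(
    member_id = "community",
    mets = tibble::tibble(id = model$mets$row, compartment = comp),
    rxns = tibble::tibble(id = model$rxns$col, lb = model$rxns$lb, ub = model$rxns$ub),
    S = model$S,
    gpr = gpr,
    biomass_reaction_id = unname(model$biomass[1])
  ), class = "member_model")
  write_member_sbml(adapter, path)
}
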