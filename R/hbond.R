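# Geometric hydrogen-bond detection and the bonds x structures SEA table
# (ensemble-average stability: fraction of conformers a bond is formed in).

#' Detect hydrogen bonds in a structure
#'
#' Geometric criteria: a donor is any N or O heavy atom with at least
#' one hydrogen within 1.2 Angstrom; an acceptor is any N or O heavy
#' atom. A bond (donor, hydrogen, acceptor) is reported iff the
#' donor-acceptor heavy-atom distance is at most `dist_cutoff` and the
#' donor-H-acceptor angle is at least `angle_cutoff`. Pairs within the
#' same residue are excluded. Keys are orientation-specific
#' (donor -> acceptor) and never deduplicated by reversal.
#'
#' @param structure an `enstab_structure` containing hydrogens.
#' @param dist_cutoff donor-acceptor heavy-atom distance cutoff,
#'   Angstrom (default 3.0).
#' @param angle_cutoff donor-H-acceptor angle cutoff, degrees
#'   (default 135).
#' @return data frame with one row per bond: donor/hydrogen/acceptor
#'   identities, geometry, and a canonical `key` string
#'   `"chain:resno:donor|H->chain:resno:acceptor"`.
#' @export
detect_hbonds <- function(structure, dist_cutoff = 3.0, angle_cutoff = 135) {
  at <- structure$atoms
  xyz <- coords(structure)
  hyd <- which(at$is_hydrogen)
  if (length(hyd) == 0L) {
    stop("structure ", structure$id, " has no hydrogens; hydrogen-bond ",
         "detection needs protonated input")
  }
  heavy_no <- which(at$element %in% c("N", "O") & !at$is_hydrogen)
  if (length(heavy_no) == 0L) return(empty_hbond_table())

  # attach each hydrogen to its donor heavy atom (covalent proximity)
  hx <- xyz[hyd, , drop = FALSE]
  dx <- xyz[heavy_no, , drop = FALSE]
  donor_of_h <- integer(length(hyd))
  for (k in seq_along(hyd)) {
    d2 <- colSums((t(dx) - hx[k, ])^2)
    j <- which.min(d2)
    donor_of_h[k] <- if (d2[j] <= 1.2^2) heavy_no[j] else NA_integer_
  }
  keep <- !is.na(donor_of_h)
  hyd <- hyd[keep]
  donor_of_h <- donor_of_h[keep]
  if (length(hyd) == 0L) return(empty_hbond_table())

  # candidate donor-acceptor pairs within the distance cutoff
  rows <- list()
  rkey <- paste(at$chain, at$resno, at$insert)
  acc_xyz <- xyz[heavy_no, , drop = FALSE]
  for (k in seq_along(hyd)) {
    d <- donor_of_h[k]
    h <- hyd[k]
    dd <- sqrt(colSums((t(acc_xyz) - xyz[d, ])^2))
    cand <- which(dd <= dist_cutoff & heavy_no != d &
                    rkey[heavy_no] != rkey[d])
    if (length(cand) == 0L) next
    hv <- xyz[h, ]
    v1 <- xyz[d, ] - hv
    for (ci in cand) {
      a <- heavy_no[ci]
      v2 <- xyz[a, ] - hv
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang >= angle_cutoff) {
        rows[[length(rows) + 1L]] <- data.frame(
          don_chain = at$chain[d], don_resno = at$resno[d],
          don_insert = at$insert[d], don_name = at$name[d],
          h_name = at$name[h],
          acc_chain = at$chain[a], acc_resno = at$resno[a],
          acc_insert = at$insert[a], acc_name = at$name[a],
          dist = dd[ci], angle = ang,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) return(empty_hbond_table())
  out <- do.call(rbind, rows)
  out$key <- hbond_key(out)
  out[order(out$key), , drop = FALSE]
}

empty_hbond_table <- function() {
  data.frame(don_chain = character(0), don_resno = integer(0),
             don_insert = character(0), don_name = character(0),
             h_name = character(0), acc_chain = character(0),
             acc_resno = integer(0), acc_insert = character(0),
             acc_name = character(0), dist = numeric(0), angle = numeric(0),
             key = character(0), stringsAsFactors = FALSE)
}

#' Canonical hydrogen-bond key strings
#' @param bonds data frame as returned by [detect_hbonds()].
#' @return character vector of keys.
#' @export
hbond_key <- function(bonds) {
  sprintf("%s:%s%s:%s|%s->%s:%s%s:%s",
          bonds$don_chain, bonds$don_resno, bonds$don_insert, bonds$don_name,
          bonds$h_name,
          bonds$acc_chain, bonds$acc_resno, bonds$acc_insert, bonds$acc_name)
}

#' Parse hydrogen-bond keys back to identities
#' @param keys character vector of keys from [hbond_key()].
#' @return data frame of donor/hydrogen/acceptor identities; rows of
#'   unparseable (opaque) keys are NA with `parsed = FALSE`.
#' @export
parse_hbond_key <- function(keys) {
  pat <- "^([^:]+):([0-9]+)([A-Za-z]?):([^|]+)\\|([^-]+)->([^:]+):([0-9]+)([A-Za-z]?):(.+)$"
  m <- regmatches(keys, regexec(pat, keys))
  out <- data.frame(
    key = keys,
    don_chain = NA_character_, don_resno = NA_integer_,
    don_insert = NA_character_, don_name = NA_character_,
    h_name = NA_character_,
    acc_chain = NA_character_, acc_resno = NA_integer_,
    acc_insert = NA_character_, acc_name = NA_character_,
    parsed = FALSE, stringsAsFactors = FALSE
  )
  for (i in seq_along(keys)) {
    g <- m[[i]]
    if (length(g) == 10L) {
      out[i, c("don_chain", "don_insert", "don_name", "h_name",
               "acc_chain", "acc_insert", "acc_name")] <-
        g[c(2L, 4L, 5L, 6L, 7L, 9L, 10L)]
      out$don_resno[i] <- as.integer(g[3L])
      out$acc_resno[i] <- as.integer(g[8L])
      out$parsed[i] <- TRUE
    }
  }
  out
}

#' Assemble the SEA table from conformer ensembles
#'
#' The bond universe is the union of bonds detected in any conformer of
#' any structure; for structure m and bond i,
#' \eqn{SEA_i^m = N_i^m / n_m} where \eqn{N_i^m} is the number of m's
#' conformers in which bond i is formed and \eqn{n_m} the ensemble size
#' (55 under default settings). Bonds never seen in a structure's
#' ensemble get an explicit 0.
#'
#' @param ensembles named list of `conformer_ensemble` objects
#'   (names are structure ids).
#' @param wt_id id of the designated wild-type structure.
#' @param dist_cutoff,angle_cutoff bond criteria, see [detect_hbonds()].
#' @return object of class `sea_table`: `values` (bonds x structures
#'   matrix with key rownames), `wt_id`, `n_conformers` per structure.
#' @export
compute_sea_table <- function(ensembles, wt_id, dist_cutoff = 3.0,
                              angle_cutoff = 135) {
  if (is.null(names(ensembles)) || any(names(ensembles) == "")) {
    stop("ensembles must be a named list")
  }
  if (!wt_id %in% names(ensembles)) stop("wt_id ", wt_id, " not in ensembles")
  if (any(vapply(ensembles, function(e) length(e$conformers), 1L) == 0L)) {
    stop("empty ensemble supplied")
  }
  counts <- lapply(ensembles, function(ens) {
    keys <- unlist(lapply(ens$conformers, function(s) {
      # unique per conformer: a bond is formed or not; two hydrogens
      # that happen to yield the same (donor, H-name, acceptor) key in
      # a distorted conformation still count once
      unique(detect_hbonds(s, dist_cutoff, angle_cutoff)$key)
    }))
    table(keys)
  })
  n_conf <- vapply(ensembles, function(e) length(e$conformers), 1L)
  if (length(unique(n_conf)) > 1L) {
    warning("unequal ensemble sizes; per-structure denominators used")
  }
  universe <- sort(unique(unlist(lapply(counts, names))))
  values <- matrix(0, nrow = length(universe), ncol = length(ensembles),
                   dimnames = list(universe, names(ensembles)))
  for (m in names(ensembles)) {
    values[names(counts[[m]]), m] <- as.numeric(counts[[m]]) / n_conf[[m]]
  }
  new_sea_table(values, wt_id, n_conf)
}

new_sea_table <- function(values, wt_id, n_conformers) {
  if (!wt_id %in% colnames(values)) stop("wt_id ", wt_id, " not a column")
  if (any(values < 0 | values > 1)) stop("SEA values must lie in [0, 1]")
  structure(list(values = values, wt_id = wt_id,
                 n_conformers = n_conformers),
            class = "sea_table")
}

#' @export
print.sea_table <- function(x, ...) {
  cat(sprintf("<sea_table> %d bonds x %d structures (WT = %s)\n",
              nrow(x$values), ncol(x$values), x$wt_id))
  invisible(x)
}

#' Write a SEA table as TSV
#'
#' Columns: `bond` (canonical key), then one numeric column per
#' structure id.
#'
#' @param sea a `sea_table`.
#' @param path output path.
#' @export
write_sea_table <- function(sea, path) {
  # 17 significant digits: doubles survive the text round-trip exactly
  num <- apply(sea$values, 2L, function(v) sprintf("%.17g", v))
  df <- data.frame(bond = rownames(sea$values), num,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("bond", colnames(sea$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bond-stability table (SEA or MD-derived STA) from TSV
#'
#' Expects one bond-identifier column (named `bond`, or detected as the
#' single non-numeric column) plus one numeric column per structure.
#' Values outside [0, 1] and duplicate bond rows are errors. Identifier
#' parsing back to donor/acceptor identities is attempted but opaque
#' labels are kept as-is.
#'
#' @param path TSV file path.
#' @param wt_column name of the wild-type column.
#' @param n_conformers ensemble size behind the values (metadata only).
#' @return a `sea_table`.
#' @export
read_stability_table <- function(path, wt_column, n_conformers = 55L) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  is_num <- vapply(df, is.numeric, TRUE)
  id_col <- if ("bond" %in% names(df)) "bond" else {
    nn <- names(df)[!is_num]
    if (length(nn) != 1L) {
      stop("cannot identify the bond-identifier column in ", path,
           " (non-numeric columns: ", paste(nn, collapse = ", "), ")")
    }
    message("using '", nn, "' as the bond-identifier column")
    nn
  }
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids)) {
    stop("duplicate bond rows: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 3L), collapse = "; "))
  }
  vals <- as.matrix(df[, setdiff(names(df), id_col), drop = FALSE])
  bad <- which(vals < 0 | vals > 1 | is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("stability value out of [0, 1] at row %d ('%s'), column '%s'",
                 bad[1L, 1L], ids[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]))
  }
  rownames(vals) <- ids
  if (!wt_column %in% colnames(vals)) {
    stop("wt column '", wt_column, "' not found; columns: ",
         paste(colnames(vals), collapse = ", "))
  }
  n_conf <- stats::setNames(rep(as.integer(n_conformers), ncol(vals)),
                            colnames(vals))
  new_sea_table(vals, wt_column, n_conf)
}
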