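#' Construct and validate a species trait table
#'
#' A trait table is a `data.frame` with one row per species, a `species`
#' column of unique labels, a `mycorrhizal_type` column with values `"AMF"`
#' or `"EMF"`, and at least one further column per functional trait. Trait
#' columns may be numeric (e.g. seed mass in mg, maximum height in m) or
#' categorical (character/factor/logical).
#'
#' @param x data.frame in the layout above.
#' @return `x` with class `trait_table` prepended, validated.
#' @export
#' @examples
#' tt <- trait_table(data.frame(
#'   species = c("sp1", "sp2"),
#'   mycorrhizal_type = c("AMF", "EMF"),
#'   seed_mass_mg = c(4, 80)))
trait_table <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("species", "mycorrhizal_type")
  if (!all(need %in% names(x)))
    stop("trait table needs columns 'species' and 'mycorrhizal_type'")
  x$species <- as.character(x$species)
  x$mycorrhizal_type <- as.character(x$mycorrhizal_type)
  if (anyDuplicated(x$species))
    stop("duplicated species labels: ",
         paste(unique(x$species[duplicated(x$species)]), collapse = ", "))
  bad <- !x$mycorrhizal_type %in% c("AMF", "EMF")
  if (any(bad))
    stop("mycorrhizal_type must be 'AMF' or 'EMF' (offending: ",
         paste(unique(x$mycorrhizal_type[bad]), collapse = ", "), ")")
  tr <- setdiff(names(x), need)
  if (length(tr) == 0L) stop("trait table needs at least one trait column")
  for (cl in tr) {
    v <- x[[cl]]
    if (all(is.na(v))) stop("trait '", cl, "' is entirely missing")
    if (is.numeric(v) && any(!is.finite(v[!is.na(v)])))
      stop("trait '", cl, "' has non-finite values")
  }
  row_all_na <- apply(as.data.frame(x[tr]), 1L, function(r) all(is.na(r)))
  if (any(row_all_na))
    stop("species with all traits missing: ",
         paste(x$species[row_all_na], collapse = ", "))
  class(x) <- unique(c("trait_table", class(x)))
  x
}

#' Read a trait table from CSV
#'
#' Expected header: `species, mycorrhizal_type, <trait>, <trait>, ...`.
#' A sidecar JSON file with the same path plus `.json` (if present) documents
#' trait units and is attached as the `"units"` attribute.
#'
#' @param path CSV file path.
#' @return a [trait_table()].
#' @export
read_trait_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  tt <- trait_table(x)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    attr(tt, "units") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  tt
}

trait_columns <- function(tt) setdiff(names(tt), c("species", "mycorrhizal_type"))

#' Gower dissimilarity for mixed-type trait tables
#'
#' Numeric traits contribute the range-normalized absolute difference
#' `|x_i - x_j| / range`, categorical traits a 0/1 mismatch indicator; the
#' per-pair dissimilarity is the mean over traits observed in both species
#' (pairwise deletion). Numeric traits with zero range carry no information
#' and are dropped with a warning.
#'
#' @param table a [trait_table()] (or coercible data.frame).
#' @return symmetric numeric matrix with species labels as dimnames, zero
#'   diagonal, entries in `[0, 1]`.
#' @export
#' @examples
#' tt <- trait_table(data.frame(
#'   species = c("a", "b", "c"),
#'   mycorrhizal_type = c("AMF", "AMF", "EMF"),
#'   height = c(0, 5, 10)))
#' gower_distance(tt)   # d(a,b) = 0.5, d(a,c) = 1
gower_distance <- function(table) {
  tt <- if (inherits(table, "trait_table")) table else trait_table(table)
  n <- nrow(tt)
  if (n < 2L) stop("need at least two species to compute dissimilarities")
  traits <- trait_columns(tt)
  num <- numer <- denom <- matrix(0, n, n)
  used <- 0L
  for (cl in traits) {
    v <- tt[[cl]]
    obs <- !is.na(v)
    w <- outer(obs, obs, "&") * 1
    if (is.numeric(v)) {
      rng <- diff(range(v, na.rm = TRUE))
      if (rng == 0) {
        warning("dropping numeric trait '", cl, "' with zero range")
        next
      }
      d <- abs(outer(v, v, "-")) / rng
      d[is.na(d)] <- 0
    } else {
      vc <- as.character(v)
      d <- outer(vc, vc, "!=") * 1
      d[is.na(d)] <- 0
    }
    numer <- numer + d * w
    denom <- denom + w
    used <- used + 1L
  }
  if (used == 0L) stop("no usable trait columns after dropping zero-range traits")
  if (any(denom[upper.tri(denom)] == 0))
    stop("some species pairs share no observed traits")
  d <- numer / denom
  diag(d) <- 0
  dimnames(d) <- list(tt$species, tt$species)
  d
}

#' Rao's quadratic entropy
#'
#' `Q = sum_i sum_j d(i, j) p_i p_j` — the abundance-weighted mean pairwise
#' dissimilarity of a community, computed as the full double sum with
#' `d(i, i) = 0`.
#'
#' @param d symmetric dissimilarity matrix (e.g. from [gower_distance()]).
#' @param p abundance vector: nonnegative, summing to 1 (tolerance `1e-9`),
#'   same length/order as the rows of `d`. Defaults to equal abundances.
#' @return scalar Q.
#' @export
#' @examples
#' d <- matrix(c(0, 1, 1, 0), 2)
#' rao_q(d, c(0.5, 0.5))  # 0.5
rao_q <- function(d, p = rep(1 / nrow(d), nrow(d))) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (length(p) != nrow(d))
    stop("abundance vector length does not match the dissimilarity matrix")
  if (any(p < 0)) stop("abundances must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9) stop("abundances must sum to 1 (tolerance 1e-9)")
  if (max(abs(d - t(d))) > 1e-12) stop("dissimilarity matrix must be symmetric")
  drop(t(p) %*% d %*% p)
}

#' Select matched AMF and EMF species pools
#'
#' Picks one pool of `pool_size` species per mycorrhizal type so that the
#' two pools are as similar as possible in their functional traits: the
#' objective is the mean between-pool pairwise Gower dissimilarity, which is
#' minimized. With at most `exhaustive_limit` candidates per type all
#' `C(n_A, k) x C(n_E, k)` pool pairs are enumerated; beyond that a seeded
#' random-restart single-swap descent is used. Ties are broken by the
#' lexicographic order of the combined, sorted species labels.
#'
#' Each selected pool's Rao Q under equal abundances is reported as a
#' functional-diversity diagnostic.
#'
#' @param table a [trait_table()] containing candidates of both types.
#' @param pool_size species per pool (default 5).
#' @param exhaustive_limit max candidates per type for exhaustive search.
#' @param seed seed for the heuristic path.
#' @param n_restarts random restarts for the heuristic path.
#' @return object of class `species_pools`: list with `amf_pool`, `emf_pool`
#'   (sorted species labels), `objective_value`, `q_amf`, `q_emf`, `method`.
#' @export
select_pools <- function(table, pool_size = 5L, exhaustive_limit = 12L,
                         seed = 1L, n_restarts = 25L) {
  tt <- if (inherits(table, "trait_table")) table else trait_table(table)
  d <- gower_distance(tt)
  amf <- sort(tt$species[tt$mycorrhizal_type == "AMF"])
  emf <- sort(tt$species[tt$mycorrhizal_type == "EMF"])
  if (length(amf) < pool_size || length(emf) < pool_size)
    stop("need at least ", pool_size, " candidate species per mycorrhizal type")
  D <- d[amf, emf, drop = FALSE]

  exhaustive <- length(amf) <= exhaustive_limit && length(emf) <= exhaustive_limit
  if (exhaustive) {
    subs_a <- utils::combn(length(amf), pool_size)
    subs_e <- utils::combn(length(emf), pool_size)
    # row sums of D over each AMF subset, then sum those over each EMF subset
    ra <- apply(subs_a, 2L, function(a) colSums(D[a, , drop = FALSE]))
    ie <- apply(subs_e, 2L, function(e) as.numeric(seq_along(emf) %in% e))
    obj <- t(ra) %*% ie / pool_size^2
    best <- min(obj)
    hit <- which(obj - best <= 1e-12, arr.ind = TRUE)
    keys <- apply(hit, 1L, function(ij) {
      paste(sort(c(amf[subs_a[, ij[1]]], emf[subs_e[, ij[2]]])), collapse = "|")
    })
    pick <- hit[order(keys)[1L], ]
    sel_a <- amf[subs_a[, pick[1L]]]
    sel_e <- emf[subs_e[, pick[2L]]]
    best_obj <- obj[pick[1L], pick[2L]]
  } else {
    res <- with_seed(seed, {
      best_obj <- Inf; sel_a <- sel_e <- NULL
      for (r in seq_len(n_restarts)) {
        a <- sort(sample(seq_along(amf), pool_size))
        e <- sort(sample(seq_along(emf), pool_size))
        repeat {
          improved <- FALSE
          cur <- mean(D[a, e])
          for (i in seq_along(a)) for (cand in setdiff(seq_along(amf), a)) {
            a2 <- a; a2[i] <- cand
            if (mean(D[a2, e]) < cur - 1e-15) { a <- sort(a2); cur <- mean(D[a, e]); improved <- TRUE }
          }
          for (i in seq_along(e)) for (cand in setdiff(seq_along(emf), e)) {
            e2 <- e; e2[i] <- cand
            if (mean(D[a, e2]) < cur - 1e-15) { e <- sort(e2); cur <- mean(D[a, e]); improved <- TRUE }
          }
          if (!improved) break
        }
        cur <- mean(D[a, e])
        key <- paste(sort(c(amf[a], emf[e])), collapse = "|")
        if (cur < best_obj - 1e-12 ||
            (abs(cur - best_obj) <= 1e-12 && !is.null(sel_a) &&
             key < paste(sort(c(sel_a, sel_e)), collapse = "|"))) {
          best_obj <- cur; sel_a <- amf[a]; sel_e <- emf[e]
        }
      }
      list(a = sel_a, e = sel_e, obj = best_obj)
    })
    sel_a <- res$a; sel_e <- res$e; best_obj <- res$obj
  }

  pool_q <- function(sp) {
    if (length(sp) < 2L) return(0)
    rao_q(d[sp, sp, drop = FALSE])
  }
  structure(list(
    amf_pool = sort(sel_a), emf_pool = sort(sel_e),
    objective_value = as.numeric(best_obj),
    q_amf = pool_q(sel_a), q_emf = pool_q(sel_e),
    method = if (exhaustive) "exhaustive" else "swap-search"
  ), class = "species_pools")
}

#' @export
print.species_pools <- function(x, ...) {
  cat("Species pools (", x$method, " search)\n", sep = "")
  cat("  AMF:", paste(x$amf_pool, collapse = ", "), "\n")
  cat("  EMF:", paste(x$emf_pool, collapse = ", "), "\n")
  cat(sprintf("  mean between-pool Gower dissimilarity: %.4f\n", x$objective_value))
  cat(sprintf("  Rao Q (equal abundances): AMF %.4f, EMF %.4f\n", x$q_amf, x$q_emf))
  invisible(x)
}

#' Construct species pools directly from label vectors
#'
#' Convenience constructor used when the pools are already known (e.g. the
#' published species list) and only downstream design/simulation is needed.
#'
#' @param amf,emf character vectors of species labels (disjoint).
#' @return a `species_pools` object with `NA` objective/diagnostics.
#' @export
species_pools <- function(amf, emf) {
  amf <- sort(as.character(amf)); emf <- sort(as.character(emf))
  if (length(intersect(amf, emf)) > 0) stop("pools must be disjoint")
  if (anyDuplicated(amf) || anyDuplicated(emf)) stop("duplicated species in a pool")
  structure(list(amf_pool = amf, emf_pool = emf, objective_value = NA_real_,
                 q_amf = NA_real_, q_emf = NA_real_, method = "given"),
            class = "species_pools")
}
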