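## Tiling of a large ROI into overlapping Cas9-excised sub-ROIs, and
## assignment of guides to reaction pools.
##
## A sub-ROI "fragment" is the excised piece between two blunt cuts:
## 0-based half-open [left_cut_position + 1, right_cut_position + 1), i.e.
## inclusive of the first retained base right of the left cut through the
## last base left of the right cut.

new_tiling_plan <- function(roi, subrois, guides, params) {
  structure(list(roi = roi, subrois = subrois, guides = guides,
                 params = params),
            class = "tiling_plan")
}

#' @export
print.tiling_plan <- function(x, ...) {
  cat("<tiling_plan> ROI ", format_region_string(x$roi), "\n", sep = "")
  tab <- plan_table(x)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Tabular view of a tiling plan
#'
#' One row per sub-ROI with 1-based inclusive fragment coordinates, the
#' flanking guide identifiers, pool, and the truncated length in kbp
#' (publication dialect).
#'
#' @param plan A `tiling_plan`.
#' @return `data.frame`.
#' @export
plan_table <- function(plan) {
  s <- plan$subrois
  data.frame(
    subroi = ifelse(is.na(s$pool), sprintf("SubROI%d", s$index),
                    sprintf("SubROI%d_%s", s$index, s$pool)),
    contig = s$contig,
    start = s$start + 1,
    end = s$end,
    length_kbp = subroi_length_kbp(s$end - s$start),
    left_guide = s$left_id,
    right_guide = s$right_id,
    pool = s$pool,
    stringsAsFactors = FALSE
  )
}

#' Sub-ROI length in kbp, truncated
#'
#' Fragment lengths are reported in kbp truncated (not rounded) to one
#' decimal, the convention under which the published sub-ROI lengths are
#' reproduced exactly from the printed guide coordinates.
#'
#' @param length_bp Fragment length(s) in bp.
#' @return Numeric vector, kbp with one truncated decimal.
#' @examples
#' subroi_length_kbp(48663)  # 48.6
#' @export
subroi_length_kbp <- function(length_bp) {
  floor(length_bp / 100) / 10
}

#' Build guide candidates from a published panel table
#'
#' Converts a crRNA table in the publication dialect (1-based coordinates;
#' minus-strand guides written start > end, 5'->3' along the minus strand)
#' into the internal candidate representation with normalised intervals,
#' strand flags and blunt cut positions.
#'
#' @param panel `data.frame` with columns `id`, `protospacer`, `pam`,
#'   `contig`, `start`, `end` (1-based publication dialect).
#' @return Candidate table as produced by [scan_protospacers()].
#' @export
panel_to_candidates <- function(panel) {
  strand <- ifelse(panel$start <= panel$end, "+", "-")
  lo <- pmin(panel$start, panel$end)
  hi <- pmax(panel$start, panel$end)
  cands <- data.frame(
    id = as.character(panel$id),
    protospacer = toupper(panel$protospacer),
    pam = toupper(panel$pam),
    contig = as.character(panel$contig),
    start = lo - 1,
    end = hi,
    strand = strand,
    stringsAsFactors = FALSE
  )
  cands$cut_position <- cut_site(cands)
  cands
}

#' Read a guide panel TSV
#'
#' @param path TSV with columns `id`, `protospacer`, `pam`, `contig`,
#'   `start`, `end` and optionally `subroi`; coordinates in the publication
#'   dialect (see [panel_to_candidates()]). Thousands separators allowed.
#' @return Candidate table.
#' @export
read_guide_panel <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "protospacer", "pam", "contig", "start", "end")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("guide panel is missing column(s): ", paste(missing, collapse = ", "))
  }
  for (cc in c("start", "end")) {
    tab[[cc]] <- as.numeric(gsub(",", "", tab[[cc]], fixed = TRUE))
  }
  panel_to_candidates(tab)
}

#' Assemble a tiling plan from an ordered guide pairing
#'
#' Pairs guides two by two in table order (left, right, left, right, ...)
#' and builds the corresponding sub-ROI fragments. Used to reconstruct a
#' plan from a published panel; for de novo design see [plan_tiling()].
#'
#' @param candidates Candidate table; `2k` rows define `k` sub-ROIs.
#' @param roi Optional [genomic_interval()] for the ROI; defaults to the
#'   span from the first to the last cut.
#' @return A `tiling_plan` (pools unassigned; see [assign_pools()]).
#' @export
pair_guides <- function(candidates, roi = NULL) {
  n <- nrow(candidates)
  if (n %% 2L != 0L || n == 0L) {
    stop("expected an even, positive number of guides; got ", n)
  }
  li <- seq(1L, n, by = 2L)
  ri <- li + 1L
  subrois <- data.frame(
    index = seq_along(li),
    contig = candidates$contig[li],
    start = candidates$cut_position[li] + 1,
    end = candidates$cut_position[ri] + 1,
    left_id = candidates$id[li],
    right_id = candidates$id[ri],
    pool = NA_character_,
    stringsAsFactors = FALSE
  )
  if (any(subrois$end <= subrois$start)) {
    stop("guide pairing produced an empty or inverted fragment")
  }
  if (is.null(roi)) {
    roi <- genomic_interval(subrois$contig[1L], min(subrois$start),
                            max(subrois$end))
  }
  new_tiling_plan(roi, subrois, candidates,
                  params = list(target_length = NA_real_,
                                overlap_min = NA_real_,
                                overlap_max = NA_real_))
}

#' Design a tiling plan over a region of interest
#'
#' Splits the ROI into `k = ceiling(length / target_length)` overlapping
#' sub-ROIs, each flanked by two guides, and selects actual cut sites from
#' the candidate set greedily left to right:
#' * the first sub-ROI starts at the candidate cut nearest the ROI start;
#' * sub-ROI *i*'s right cut is the candidate nearest its ideal boundary
#'   (evenly interpolated across the ROI; the last boundary is the ROI end);
#' * sub-ROI *i+1*'s left cut is the candidate placing the overlap with
#'   sub-ROI *i* inside `[overlap_min, overlap_max]`, as close to
#'   `overlap_min` as possible.
#' Ties are broken toward the smaller coordinate. Each sub-ROI receives
#' exactly two guides and no guide is shared between sub-ROIs.
#'
#' @param roi [genomic_interval()] to tile.
#' @param candidates Candidate table (e.g. the PASS set from
#'   [filter_candidates()]), with `cut_position` populated.
#' @param target_length Ideal sub-ROI length in bp (default 50,000).
#' @param overlap_min,overlap_max Allowed overlap between consecutive
#'   sub-ROIs in bp (defaults 2,000 and 4,000).
#' @param boundary_window Maximum distance in bp between an ideal boundary
#'   and the selected cut site (default 5,000).
#' @return A `tiling_plan` with pools unassigned.
#' @export
plan_tiling <- function(roi, candidates, target_length = 50000,
                        overlap_min = 2000, overlap_max = 4000,
                        boundary_window = 5000) {
  stopifnot(inherits(roi, "genomic_interval"))
  cands <- candidates[candidates$contig == roi$contig, , drop = FALSE]
  if (nrow(cands) == 0L) stop("no candidates on contig ", roi$contig)
  cands <- cands[order(cands$cut_position), , drop = FALSE]
  ## cut boundary: 0-based insertion point of the blunt cut
  bnd <- cands$cut_position + 1

  len <- interval_length(roi)
  k <- ceiling(len / target_length)

  nearest <- function(target, eligible = rep(TRUE, length(bnd))) {
    idx <- which(eligible)
    if (!length(idx)) return(NA_integer_)
    d <- abs(bnd[idx] - target)
    ## tie toward the smaller coordinate
    idx[order(d, bnd[idx])][1L]
  }

  used <- logical(nrow(cands))
  left_idx <- integer(k)
  right_idx <- integer(k)

  i1 <- nearest(roi$start, !used)
  if (is.na(i1) || abs(bnd[i1] - roi$start) > boundary_window) {
    stop("no candidate cut within ", boundary_window,
         " bp of the ROI start (", format_region_string(roi), ")")
  }
  left_idx[1L] <- i1
  used[i1] <- TRUE

  for (i in seq_len(k)) {
    ideal <- if (i < k) roi$start + round(i * len / k) else roi$end
    j <- nearest(ideal, !used & bnd > bnd[left_idx[i]])
    if (is.na(j) || abs(bnd[j] - ideal) > boundary_window) {
      stop("no candidate cut within ", boundary_window,
           " bp of the ideal sub-ROI boundary at ",
           format(ideal + 1, big.mark = ","), " (sub-ROI ", i, ")")
    }
    right_idx[i] <- j
    used[j] <- TRUE
    if (i < k) {
      ## overlap with sub-ROI i is bnd[right_i] - b; want it in
      ## [overlap_min, overlap_max], nearest overlap_min
      o <- bnd[right_idx[i]] - bnd
      ok <- !used & o >= overlap_min & o <= overlap_max
      if (!any(ok)) {
        stop("no candidate places the overlap between sub-ROIs ", i,
             " and ", i + 1L, " inside [", overlap_min, ", ", overlap_max,
             "] bp; nearest gap is around ",
             format(bnd[right_idx[i]], big.mark = ","))
      }
      jj <- which(ok)
      jj <- jj[order(o[jj], bnd[jj])][1L]
      left_idx[i + 1L] <- jj
      used[jj] <- TRUE
    }
  }

  subrois <- data.frame(
    index = seq_len(k),
    contig = roi$contig,
    start = bnd[left_idx],
    end = bnd[right_idx],
    left_id = cands$id[left_idx],
    right_id = cands$id[right_idx],
    pool = NA_character_,
    stringsAsFactors = FALSE
  )
  guides <- cands[sort(c(left_idx, right_idx)), , drop = FALSE]
  rownames(guides) <- NULL
  new_tiling_plan(roi, subrois, guides,
                  params = list(target_length = target_length,
                                overlap_min = overlap_min,
                                overlap_max = overlap_max))
}

## Sub-ROI conflict matrix: TRUE when fragments overlap, i.e. each has a
## boundary cut strictly inside the other.
subroi_conflicts <- function(subrois) {
  k <- nrow(subrois)
  conf <- matrix(FALSE, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j && subrois$contig[i] == subrois$contig[j]) {
        conf[i, j] <- subrois$start[i] < subrois$end[j] &&
                      subrois$start[j] < subrois$end[i]
      }
    }
  }
  conf
}

#' Assign guides to reaction pools
#'
#' Guides of overlapping sub-ROIs must go to different pools, or a pool's
#' cuts would fall inside a fragment that same pool is meant to liberate.
#' Builds the conflict graph on sub-ROIs (edge when fragments overlap) and
#' colours it greedily in index order; for the chain designs produced by
#' [plan_tiling()] this is optimal and yields two pools with odd/even
#' alternation (one pool for a single tile or mutually disjoint tiles).
#'
#' @param plan A `tiling_plan`.
#' @return The plan with `subrois$pool` populated (`"P1"`, `"P2"`, ...).
#' @export
assign_pools <- function(plan) {
  stopifnot(inherits(plan, "tiling_plan"))
  s <- plan$subrois
  conf <- subroi_conflicts(s)
  colour <- integer(nrow(s))
  for (i in seq_len(nrow(s))) {
    taken <- colour[which(conf[i, ] & colour > 0L)]
    colour[i] <- min(setdiff(seq_len(i), taken))
  }
  plan$subrois$pool <- paste0("P", colour)
  plan
}

#' Pool membership of guides
#'
#' @param plan A pooled `tiling_plan`.
#' @return Named list mapping pool id to the guide ids it contains.
#' @export
pool_guides <- function(plan) {
  s <- plan$subrois
  if (anyNA(s$pool)) stop("plan has unassigned pools; run assign_pools()")
  pools <- sort(unique(s$pool))
  setNames(lapply(pools, function(p) {
    rows <- s[s$pool == p, , drop = FALSE]
    unique(c(rbind(rows$left_id, rows$right_id)))
  }), pools)
}

#' Validate a tiling plan
#'
#' Checks the plan against the design constraints and returns a violation
#' report (empty when the plan is valid):
#' * `gap` — consecutive sub-ROIs leave uncovered bases between them;
#' * `overlap_bounds` — a consecutive overlap falls outside
#'   `[overlap_min, overlap_max]`;
#' * `internal_cut` — two sub-ROIs sharing a pool overlap, so each pool
#'   reaction cuts inside a fragment it must liberate (reported once per
#'   conflicting pair);
#' * `shared_guide` — a guide flanks more than one sub-ROI.
#'
#' @param plan A `tiling_plan`.
#' @param overlap_min,overlap_max Overlap bounds; default to the plan's own
#'   parameters (checks skipped when those are `NA`).
#' @return `data.frame` with columns `type`, `subroi_a`, `subroi_b`,
#'   `detail`; zero rows iff the plan is valid.
#' @export
validate_plan <- function(plan, overlap_min = plan$params$overlap_min,
                          overlap_max = plan$params$overlap_max) {
  stopifnot(inherits(plan, "tiling_plan"))
  s <- plan$subrois
  viol <- list()
  add <- function(type, a, b, detail) {
    viol[[length(viol) + 1L]] <<- data.frame(
      type = type, subroi_a = a, subroi_b = b, detail = detail,
      stringsAsFactors = FALSE)
  }
  k <- nrow(s)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      o <- s$end[i] - s$start[i + 1L]
      if (o <= 0) {
        add("gap", i, i + 1L,
            sprintf("%d uncovered bp between sub-ROIs", -o))
      } else if (!is.na(overlap_min) && (o < overlap_min || o > overlap_max)) {
        add("overlap_bounds", i, i + 1L,
            sprintf("overlap %d bp outside [%d, %d]", as.integer(o),
                    as.integer(overlap_min), as.integer(overlap_max)))
      }
    }
  }
  if (!anyNA(s$pool)) {
    conf <- subroi_conflicts(s)
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (i < j && conf[i, j] && s$pool[i] == s$pool[j]) {
          add("internal_cut", i, j,
              sprintf("sub-ROIs %d and %d overlap but share pool %s",
                      i, j, s$pool[i]))
        }
      }
    }
  }
  ids <- c(s$left_id, s$right_id)
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) {
    add("shared_guide", NA_integer_, NA_integer_,
        sprintf("guide %s flanks more than one sub-ROI", d))
  }
  if (length(viol)) do.call(rbind, viol)
  else data.frame(type = character(0), subroi_a = integer(0),
                  subroi_b = integer(0), detail = character(0),
                  stringsAsFactors = FALSE)
}
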