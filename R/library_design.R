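# Combinatorial STARR-seq library design: screened synthetic background
# sequence, slot-assignment enumeration, oligo rendering, control tiling
# and cloning flanks.

#' Design a motif-free synthetic background sequence
#'
#' Generates a random sequence, scans it for every screened motif and
#' mutates positions inside hit windows (uniform random substitution to a
#' different base), repeating until no motif hits remain. Reproducible for
#' a fixed seed.
#'
#' @param length sequence length in bp (default 125).
#' @param motifs list of `pwm` (or [ppm]) objects to screen against; an
#'   empty list returns the first random draw unmodified.
#' @param p_thresh,score_min,granularity scan thresholds, as in
#'   [scan_sequences()].
#' @param seed RNG seed.
#' @param max_rounds mutation rounds before giving up (default 100).
#' @return object of class `background_sequence`: list with `sequence`,
#'   `screened_motifs` (ids), `seed`, `rounds`.
#' @export
design_background <- function(length = 125, motifs = list(),
                              p_thresh = 1e-4, score_min = NULL,
                              granularity = 1e-3, seed = NULL,
                              max_rounds = 100) {
  stop_if_not(max_rounds >= 1, "max_rounds must be at least 1")
  pwms <- lapply(motifs, function(p) if (is(p, "ppm")) ppm_to_pwm(p) else p)
  dists <- lapply(pwms, score_distribution, granularity = granularity)
  with_seed(seed, {
    seq_chars <- sample(DNA_BASES, length, replace = TRUE)
    rounds <- 0L
    repeat {
      s <- paste(seq_chars, collapse = "")
      hits <- do.call(rbind, lapply(seq_along(pwms), function(i) {
        scan_sequences(pwms[[i]], c(bg = s), p_thresh = p_thresh,
                       score_min = score_min, dist = dists[[i]])
      }))
      if (is.null(hits) || nrow(hits) == 0) {
        return(structure(
          list(sequence = s,
               screened_motifs = vapply(pwms, `[[`, "", "motif_id"),
               seed = seed, rounds = rounds),
          class = "background_sequence"))
      }
      rounds <- rounds + 1L
      if (rounds > max_rounds) {
        stop(sprintf(
          "background design failed: %d motif hit(s) remain after %d rounds",
          nrow(hits), max_rounds), call. = FALSE)
      }
      widths <- nchar(hits$match)
      in_hit <- unique(unlist(Map(function(o, w) seq(o + 1, o + w),
                                  hits$offset, widths)))
      for (pos in in_hit) {
        seq_chars[pos] <- sample(setdiff(DNA_BASES, seq_chars[pos]), 1)
      }
    }
  })
}

#' @export
print.background_sequence <- function(x, ...) {
  cat(sprintf("background sequence: %d bp, %d motifs screened, %d rounds\n",
              nchar(x$sequence), length(x$screened_motifs), x$rounds))
  invisible(x)
}

#' Enumerate slot assignments for the combinatorial library
#'
#' Every slot independently holds nothing or one of the motifs in forward
#' or reverse orientation, giving `(2m + 1)^n_slots` designs including the
#' all-empty background design. Slot 1 is closest to the core promoter.
#' Enumeration order is deterministic (slot 1 varies fastest; per slot:
#' empty, then each motif forward then reverse).
#'
#' @param motif_ids character vector of candidate motif ids.
#' @param n_slots number of slots (default 3).
#' @param include_empty if `FALSE`, slots must all be occupied
#'   (`(2m)^n_slots` designs, no background design).
#' @return data.frame with `oligo_id`, `slot1` ... `slotN` (entries
#'   `"motif:fwd"`, `"motif:rev"` or `"."`) and `is_background`.
#' @export
enumerate_designs <- function(motif_ids, n_slots = 3, include_empty = TRUE) {
  stop_if_not(length(motif_ids) >= 1, "need at least one motif")
  stop_if_not(!anyDuplicated(motif_ids), "motif ids must be unique")
  opts <- as.vector(t(cbind(paste0(motif_ids, ":fwd"),
                            paste0(motif_ids, ":rev"))))
  if (include_empty) opts <- c(".", opts)
  grid <- do.call(expand.grid,
                  c(rep(list(opts), n_slots),
                    list(stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)))
  names(grid) <- paste0("slot", seq_len(n_slots))
  grid <- cbind(oligo_id = sprintf("OL%06d", seq_len(nrow(grid))), grid,
                stringsAsFactors = FALSE)
  grid$is_background <- rowSums(grid[, paste0("slot", seq_len(n_slots)),
                                     drop = FALSE] != ".") == 0
  grid
}

.parse_slot <- function(slot) {
  # "motif:fwd" -> c(motif, orientation); "." -> NULL
  if (slot == ".") return(NULL)
  parts <- strsplit(slot, ":", fixed = TRUE)[[1]]
  stop_if_not(length(parts) == 2 && parts[2] %in% c("fwd", "rev"),
              sprintf("malformed slot entry '%s'", slot))
  parts
}

#' Render a slot assignment into an oligo sequence
#'
#' Occupied slots are placed left to right (slot 1 first, nearest the core
#' promoter) starting at `left_margin`; each placed site (reverse
#' orientation = reverse complement) is followed by a `spacing`-bp spacer
#' drawn from the background sequence at the corresponding background
#' coordinates, so unused positions carry identical background context
#' across oligos. Remaining positions are filled with the continuing
#' background so all oligos have identical length; the all-empty
#' assignment renders the pure background prefix.
#'
#' @param assignment character vector of slot entries (`"motif:fwd"`,
#'   `"motif:rev"`, `"."`), slot 1 first.
#' @param background background sequence (a `background_sequence` or plain
#'   string) at least as long as the background bases consumed.
#' @param sites named character vector: motif id -> representative site
#'   sequence (forward orientation).
#' @param spacing spacer length between placed sites (default 10).
#' @param oligo_len rendered length (default 88).
#' @param left_margin background bases before the first slot (default 0).
#' @return list with `assignment`, `sequence`, `copies` (named motif
#'   counts over occupied slots).
#' @export
render_oligo <- function(assignment, background, sites, spacing = 10,
                         oligo_len = 88, left_margin = 0) {
  if (is(background, "background_sequence")) background <- background$sequence
  occupied <- Filter(Negate(is.null), lapply(assignment, .parse_slot))
  placed <- vapply(occupied, function(sl) {
    site <- sites[[sl[1]]]
    stop_if_not(!is.null(site), sprintf("no site sequence for '%s'", sl[1]))
    if (sl[2] == "rev") revcomp(site) else site
  }, character(1))
  total_sites <- sum(nchar(placed))
  # content up to the last placed site (the trailing spacer merges into the
  # background fill) must fit the oligo
  content <- left_margin + total_sites +
    max(0L, length(placed) - 1L) * spacing
  if (content > oligo_len) {
    stop(sprintf("assignment [%s] overflows the %d-bp oligo (%d bp placed)",
                 paste(assignment, collapse = ", "), oligo_len, content),
         call. = FALSE)
  }
  bg_needed <- oligo_len - total_sites
  stop_if_not(nchar(background) >= bg_needed,
              "background sequence too short to fill the oligo")
  pieces <- character(0)
  bg_pos <- 0L                 # background bases consumed so far
  if (left_margin > 0) {
    pieces <- substr(background, 1, left_margin)
    bg_pos <- left_margin
  }
  for (p in placed) {
    pieces <- c(pieces, p)
    spacer <- substr(background, bg_pos + 1, bg_pos + spacing)
    pieces <- c(pieces, spacer)
    bg_pos <- bg_pos + spacing
  }
  out <- paste(pieces, collapse = "")
  if (nchar(out) < oligo_len) {
    fill <- substr(background, bg_pos + 1, bg_pos + (oligo_len - nchar(out)))
    out <- paste0(out, fill)
  } else {
    out <- substr(out, 1, oligo_len)
  }
  stop_if_not(nchar(out) == oligo_len, "internal error: short render")
  motifs <- vapply(occupied, `[`, character(1), 1)
  copies <- if (length(motifs) > 0) table(motifs) else table(character(0))
  list(assignment = assignment, sequence = out,
       copies = setNames(as.integer(copies), names(copies)))
}

#' Render a whole design table into a library manifest
#'
#' @param designs data.frame from [enumerate_designs()].
#' @inheritParams render_oligo
#' @param controls optional named character vector of control sequences
#'   (already `oligo_len` long), appended with `is_control = TRUE`.
#' @return manifest data.frame: `oligo_id`, slot columns, `sequence`,
#'   `is_background`, `is_control`. Warns if two designs collide on the
#'   same sequence.
#' @export
render_library <- function(designs, background, sites, spacing = 10,
                           oligo_len = 88, left_margin = 0, controls = NULL) {
  slot_cols <- grep("^slot", names(designs), value = TRUE)
  seqs <- vapply(seq_len(nrow(designs)), function(i) {
    render_oligo(unlist(designs[i, slot_cols], use.names = FALSE),
                 background, sites, spacing = spacing,
                 oligo_len = oligo_len, left_margin = left_margin)$sequence
  }, character(1))
  out <- cbind(designs, sequence = seqs, is_control = FALSE,
               stringsAsFactors = FALSE)
  if (!is.null(controls)) {
    stop_if_not(all(nchar(controls) == oligo_len),
                "control sequences must match oligo_len")
    ctrl_ids <- if (is.null(names(controls)))
      sprintf("CTRL%04d", seq_along(controls)) else names(controls)
    ctrl <- data.frame(oligo_id = ctrl_ids, stringsAsFactors = FALSE)
    for (sc in slot_cols) ctrl[[sc]] <- "."
    ctrl$is_background <- FALSE
    ctrl$sequence <- unname(controls)
    ctrl$is_control <- TRUE
    out <- rbind(out, ctrl)
  }
  if (anyDuplicated(out$sequence)) {
    warning("sequence collision: ", sum(duplicated(out$sequence)),
            " rendered oligo(s) duplicate another design's sequence")
  }
  rownames(out) <- NULL
  out
}

#' Tile a sequence into fixed-length windows
#'
#' All windows of `tile_len` at the given step, deduplicated keeping first
#' occurrence; a 200-bp sequence yields 113 distinct 88-bp tiles at step 1
#' (200 - 88 + 1, before deduplication).
#'
#' @param sequence character scalar.
#' @param tile_len window length (default 88).
#' @param step step between window starts (default 1).
#' @return named character vector of tiles (`tile_<start>` with 0-based
#'   start).
#' @export
tile_sequence <- function(sequence, tile_len = 88, step = 1) {
  n <- nchar(sequence)
  stop_if_not(n >= tile_len, "sequence shorter than the tile length")
  starts <- seq(1, n - tile_len + 1, by = step)
  tiles <- substring(sequence, starts, starts + tile_len - 1)
  names(tiles) <- sprintf("tile_%d", starts - 1L)
  tiles[!duplicated(tiles)]
}

#' Add restriction sites and adapters around an insert
#'
#' Builds `adapters[1] + five_site + sequence + three_site + adapters[2]`
#' (AgeI/SalI recognition sites by default) and warns when a recognition
#' site already occurs inside the insert.
#'
#' @param sequence insert sequence.
#' @param five_site,three_site restriction sites (defaults `ACCGGT` = AgeI,
#'   `GTCGAC` = SalI).
#' @param adapters length-2 character vector of 5' and 3' adapter
#'   sequences.
#' @return character scalar construct.
#' @export
add_cloning_flanks <- function(sequence, five_site = "ACCGGT",
                               three_site = "GTCGAC",
                               adapters = c("", "")) {
  if (grepl(five_site, sequence, fixed = TRUE) ||
      grepl(three_site, sequence, fixed = TRUE)) {
    warning("a restriction recognition site occurs inside the insert")
  }
  paste0(adapters[1], five_site, sequence, three_site, adapters[2])
}
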