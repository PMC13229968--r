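# Plant architecture token codec.
#
# Sequence layout:
#   SOS, META_OPEN, q(width), q(height), q(vegetation fraction), META_CLOSE,
#   q(base_pitch), q(base_yaw), q(base_roll), q(plant_age),        # header
#   then depth-first per shoot:
#     shoot token + (shoot_type, base_pitch, base_yaw, base_roll),
#     per phytomer: internode token + 4 params, petiole token + 4 (unifoliate)
#     or 5 (trifoliate, with leaflet_scale) params, 1-3 leaf tokens + 4 params
#     each, then any child shoot's block attached at that phytomer,
#   EOS.
#
# Leaf slot codes: unifoliate leaves all use slot code 3; trifoliate leaflets
# use 3, 4, 5 in order.

.SCHEMA_META <- c("meta_width", "meta_height", "meta_vegetation_fraction")
.SCHEMA_HEADER <- c("base_rotation_pitch", "base_rotation_yaw",
                    "base_rotation_roll", "plant_age")
.SCHEMA_SHOOT <- c("shoot_type_label", "shoot_base_pitch", "shoot_base_yaw",
                   "shoot_base_roll")
.SCHEMA_INTERNODE <- c("internode_length", "internode_radius",
                       "internode_pitch", "internode_phyllotactic_angle")
.SCHEMA_PETIOLE <- c("petiole_length", "petiole_radius", "petiole_pitch",
                     "petiole_curvature", "leaflet_scale")
.SCHEMA_LEAF <- c("leaf_scale", "leaf_pitch", "leaf_yaw", "leaf_roll")

#' Construct a token sequence
#'
#' A light wrapper around an integer vector of token IDs in `0..227`.
#' Structural grammar (framing, parameter counts, organ nesting) is enforced
#' by [detokenize()], which names the offending token index on failure.
#'
#' @param ids Integer vector of token IDs.
#' @return Object of class `pa_tokens` (an integer vector).
#' @export
token_sequence <- function(ids) {
  ids <- as.integer(ids)
  if (length(ids) == 0) stop("token sequence must be non-empty", call. = FALSE)
  if (any(is.na(ids)) || any(ids < 0L) || any(ids > 227L))
    stop("token IDs must be integers in 0..227", call. = FALSE)
  structure(ids, class = "pa_tokens")
}

#' @export
print.pa_tokens <- function(x, ...) {
  n <- length(x)
  head_ids <- paste(utils::head(unclass(x), 18), collapse = " ")
  cat(sprintf("<token sequence> %d tokens: %s%s\n", n, head_ids,
              if (n > 18) " ..." else ""))
  invisible(x)
}

.q <- function(values, names, vocab) {
  out <- integer(length(values))
  for (i in seq_along(values))
    out[i] <- quantize_parameter(values[i], names[i], vocab)
  out
}

#' Tokenize a plant architecture
#'
#' Serializes an architecture and its image metadata into the integer token
#' sequence described in the package vignette: special-token framing, three
#' metadata parameter tokens, a four-token plant header (base rotation and
#' age), then one block per shoot in depth-first order with child shoots
#' emitted immediately after the phytomer where they attach.
#'
#' @param plant A valid [plant_architecture()]; branching orders must be <= 3.
#' @param meta A [plant_metadata()] object.
#' @param vocab A [build_vocabulary()] object.
#' @return A [token_sequence()].
#' @export
tokenize_architecture <- function(plant, meta = plant_metadata(0, 0, 0),
                                  vocab = build_vocabulary()) {
  if (!inherits(plant, "pa_plant") || length(plant$shoots) == 0)
    stop("unsupported topology: plant must contain at least one shoot", call. = FALSE)
  orders <- vapply(plant$shoots, function(s) s$branching_order, integer(1))
  if (any(orders > 3L))
    stop("unsupported topology: branching order exceeds 3", call. = FALSE)

  ids <- vapply(plant$shoots, function(s) s$shoot_id, integer(1))
  parent <- vapply(plant$shoots, function(s) s$parent_shoot_id, integer(1))
  pnode <- vapply(plant$shoots, function(s) s$parent_node_index, integer(1))

  acc <- vector("list", 64); n_acc <- 0L
  push <- function(x) {
    n_acc <<- n_acc + 1L
    if (n_acc > length(acc)) length(acc) <<- 2L * n_acc
    acc[[n_acc]] <<- x
  }

  emit_shoot <- function(si) {
    s <- plant$shoots[[si]]
    b <- s$branching_order
    push(c(organ_token(b, 0L),
           .q(c(s$shoot_type_label, s$base_pitch, s$base_yaw, s$base_roll),
              .SCHEMA_SHOOT, vocab)))
    for (k in seq_along(s$phytomers)) {
      ph <- s$phytomers[[k]]
      push(c(organ_token(b, 1L),
             .q(c(ph$internode$length, ph$internode$radius, ph$internode$pitch,
                  ph$internode$phyllotactic_angle), .SCHEMA_INTERNODE, vocab)))
      pet <- ph$petiole
      pet_vals <- c(pet$length, pet$radius, pet$pitch, pet$curvature)
      if (!is.null(pet$leaflet_scale)) pet_vals <- c(pet_vals, pet$leaflet_scale)
      push(c(organ_token(b, 2L), .q(pet_vals, .SCHEMA_PETIOLE, vocab)))
      tri <- !is.null(pet$leaflet_scale)
      for (l in seq_along(ph$leaves)) {
        lf <- ph$leaves[[l]]
        code <- if (tri) 2L + l else 3L
        push(c(organ_token(b, code),
               .q(c(lf$scale, lf$pitch, lf$yaw, lf$roll), .SCHEMA_LEAF, vocab)))
      }
      kids <- which(parent == s$shoot_id & pnode == (k - 1L))
      for (ci in kids) emit_shoot(ci)
    }
  }

  sp <- vocab$special_tokens
  push(c(sp[["SOS"]], sp[["META_OPEN"]]))
  push(.q(c(meta$width_m, meta$height_m, meta$vegetation_fraction),
          .SCHEMA_META, vocab))
  push(sp[["META_CLOSE"]])
  push(.q(c(plant$base_rotation, plant$plant_age), .SCHEMA_HEADER, vocab))
  root <- which(parent == -1L)
  if (length(root) != 1)
    stop("unsupported topology: plant must have exactly one primary shoot", call. = FALSE)
  emit_shoot(root)
  push(sp[["EOS"]])
  token_sequence(unlist(acc[seq_len(n_acc)], use.names = FALSE))
}

#' Decode a token sequence into a plant architecture
#'
#' Inverse of [tokenize_architecture()]. Reconstructs the organ hierarchy and
#' the quantized parameter values; `tokenize_architecture(detokenize(seq))`
#' returns `seq` exactly. Grammar violations (wrong parameter count, missing
#' EOS, orphan child order, malformed framing) raise a decode error naming
#' the 1-based token index.
#'
#' @param seq A [token_sequence()] or integer vector of token IDs.
#' @param vocab A [build_vocabulary()] object.
#' @return A list with elements `plant` ([plant_architecture()]) and
#'   `metadata` ([plant_metadata()]).
#' @export
detokenize <- function(seq, vocab = build_vocabulary()) {
  ids <- as.integer(unclass(seq))
  sp <- vocab$special_tokens
  pos <- 1L
  n <- length(ids)

  fail <- function(msg, at = pos)
    stop(sprintf("decode error at token %d: %s", at, msg), call. = FALSE)
  peek <- function() if (pos <= n) ids[pos] else NA_integer_
  take <- function() { v <- peek(); if (is.na(v)) fail("unexpected end of sequence"); pos <<- pos + 1L; v }
  expect_special <- function(name) {
    v <- take()
    if (v != sp[[name]]) fail(sprintf("expected <%s> (ID %d), got %d", name, sp[[name]], v), pos - 1L)
  }
  is_param <- function(v) !is.na(v) && v >= vocab$param_id_min && v <= vocab$param_id_max
  take_params <- function(names) {
    k <- length(names)
    out <- numeric(k)
    for (i in seq_len(k)) {
      v <- take()
      if (!is_param(v)) fail(sprintf("expected parameter token for %s, got ID %d", names[i], v), pos - 1L)
      out[i] <- dequantize(v, names[i], vocab)
    }
    out
  }

  expect_special("SOS")
  expect_special("META_OPEN")
  mvals <- take_params(.SCHEMA_META)
  expect_special("META_CLOSE")
  hdr <- take_params(.SCHEMA_HEADER)

  shoots <- list()
  next_id <- 0L

  parse_shoot <- function(order, parent_id, parent_node) {
    v <- take()
    if (is.na(v) || v != organ_token(order, 0L))
      fail(sprintf("expected shoot token of order %d (ID %d), got %d",
                   order, organ_token(order, 0L), v), pos - 1L)
    svals <- take_params(.SCHEMA_SHOOT)
    sid <- next_id; next_id <<- next_id + 1L
    slot <- length(shoots) + 1L
    shoots[slot] <<- list(NULL)  # reserve position: parent precedes children
    phyts <- list()
    repeat {
      v <- peek()
      if (is.na(v) || v >= .N_ORGAN) break           # EOS or end of organ run
      code <- v %% 6L; ord <- v %/% 6L
      if (!(ord == order && code == 1L)) break        # not our internode
      take()
      ivals <- take_params(.SCHEMA_INTERNODE)
      v <- take()
      if (is.na(v) || v != organ_token(order, 2L))
        fail(sprintf("expected petiole token of order %d, got %d", order, v), pos - 1L)
      pvals <- take_params(.SCHEMA_PETIOLE[1:4])
      leaflet <- NULL
      if (is_param(peek())) leaflet <- take_params(.SCHEMA_PETIOLE[5])
      leaves <- list()
      if (is.null(leaflet)) {
        while (!is.na(peek()) && peek() == organ_token(order, 3L)) {
          take()
          lv <- take_params(.SCHEMA_LEAF)
          leaves[[length(leaves) + 1L]] <- leaf(lv[1], lv[2], lv[3], lv[4])
          if (length(leaves) > 2L) fail("unifoliate phytomer carries more than 2 leaves", pos - 1L)
        }
        if (length(leaves) == 0L) fail("phytomer has no leaf token")
      } else {
        for (slot_code in 3:5) {
          v <- take()
          if (is.na(v) || v != organ_token(order, slot_code))
            fail(sprintf("expected trifoliate leaflet token %d%d, got %d", order, slot_code, v), pos - 1L)
          lv <- take_params(.SCHEMA_LEAF)
          leaves[[length(leaves) + 1L]] <- leaf(lv[1], lv[2], lv[3], lv[4])
        }
      }
      phyts[[length(phyts) + 1L]] <- phytomer(
        internode(ivals[1], ivals[2], ivals[3], ivals[4]),
        petiole(pvals[1], pvals[2], pvals[3], pvals[4], leaflet_scale = leaflet),
        leaves)
      # child shoots attached at this phytomer
      while (!is.na(peek()) && peek() < .N_ORGAN && peek() %% 6L == 0L &&
             peek() %/% 6L == order + 1L) {
        parse_shoot(order + 1L, sid, length(phyts) - 1L)
      }
      v <- peek()
      if (!is.na(v) && v < .N_ORGAN && v %% 6L == 0L && v %/% 6L > order + 1L)
        fail(sprintf("orphan shoot token of order %d under order-%d shoot", v %/% 6L, order))
    }
    if (length(phyts) == 0L) fail("shoot has no phytomers")
    shoots[[slot]] <<- shoot(shoot_id = sid, parent_shoot_id = parent_id,
                             parent_node_index = parent_node,
                             branching_order = order,
                             shoot_type_label = svals[1], base_pitch = svals[2],
                             base_yaw = svals[3], base_roll = svals[4],
                             phytomers = phyts)
    invisible(NULL)
  }

  parse_shoot(0L, -1L, -1L)
  expect_special("EOS")
  if (pos <= n) fail("trailing tokens after EOS")

  list(plant = plant_architecture(shoots = shoots, plant_age = hdr[4],
                                  base_rotation = hdr[1:3]),
       metadata = plant_metadata(mvals[1], mvals[2], mvals[3]))
}

# ---------------------------------------------------------------------------
# Token text format: one plant per line, space-separated integer IDs.

#' Write token sequences to a text file
#'
#' Canonical format: one plant per line, space-separated integer token IDs.
#'
#' @param seqs A token sequence or list of token sequences.
#' @param path Output file path.
#' @export
write_token_file <- function(seqs, path) {
  if (!is.list(seqs)) seqs <- list(seqs)
  lines <- vapply(seqs, function(s) paste(as.integer(unclass(s)), collapse = " "),
                  character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read token sequences from a text file
#'
#' @param path Path to a canonical token text file.
#' @return List of [token_sequence()] objects, one per line.
#' @export
read_token_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) token_sequence(as.integer(strsplit(trimws(l), "\\s+")[[1]])))
}

#' Human-readable rendering of a token sequence
#'
#' Organ tokens print as two-digit strings ("00".."35"), parameter tokens as
#' their decoded grid values and specials as `<SOS>` etc. This rendering is
#' for inspection only and is not re-ingestible (prescaled parameters decode
#' with factor 1 because the parameter identity is positional).
#'
#' @param seq A [token_sequence()].
#' @param vocab A [build_vocabulary()] object.
#' @return Character vector, one element per token.
#' @export
format_tokens_human <- function(seq, vocab = build_vocabulary()) {
  ids <- as.integer(unclass(seq))
  sp <- vocab$special_tokens
  vapply(ids, function(v) {
    if (v < .N_ORGAN) return(sprintf("%d%d", v %/% 6L, v %% 6L))
    if (v >= vocab$param_id_min && v <= vocab$param_id_max)
      return(format(vocab$param_grid[v - vocab$param_id_min + 1L]))
    sprintf("<%s>", names(sp)[match(v, sp)])
  }, character(1))
}
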