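# Fixed-row-width table store with batch-granular dirty tracking and a
# transfer ledger.  Every row occupies the same memory footprint regardless
# of occupancy; a secondary vector holds the current length of each row, so
# rows can shrink or grow (up to the fixed capacity) without any
# reallocation or shifting of other rows.  Rows are grouped into contiguous
# batches, the unit of dirty tracking and of the modeled host-to-device
# copy.  Tables use reference (environment) semantics: writeRow/flushTable
# mutate in place.

#' Create a fixed-width table
#'
#' One-time allocation: no subsequent operation ever grows or reallocates
#' the table.  `slot_cols` is the number of numeric columns backing each
#' logical item (1 for scalars/indices, 3 for gradient vectors, 2 for
#' index+weight pairs); `item_bytes` is the modeled payload size per item
#' used by the transfer ledger.
#'
#' @param n_rows number of rows (elements / vertices).
#' @param max_row_width fixed row capacity in items.
#' @param item_bytes modeled bytes per item.
#' @param batch_size rows per transfer batch (<= n_rows).
#' @param name table name used in ledger records.
#' @param slot_cols numeric columns per item in the backing payload.
#' @param length_entry_bytes modeled bytes per row-length entry (default 4).
#' @return An environment of class `FixedWidthTable`.
#' @export
createTable <- function(n_rows, max_row_width, item_bytes, batch_size,
                        name = "table", slot_cols = 1L,
                        length_entry_bytes = 4L) {
    if (any(c(n_rows, max_row_width, item_bytes, batch_size) < 1)) {
        stop(softcutError(
            "n_rows, max_row_width, item_bytes and batch_size must all be >= 1",
            "softcutArgumentError"
        ))
    }
    if (batch_size > n_rows) {
        stop(softcutError("batch_size must be <= n_rows", "softcutArgumentError"))
    }
    t <- new.env(parent = emptyenv())
    t$n_rows <- as.integer(n_rows)
    t$max_row_width <- as.integer(max_row_width)
    t$item_bytes <- as.integer(item_bytes)
    t$batch_size <- as.integer(batch_size)
    t$slot_cols <- as.integer(slot_cols)
    t$length_entry_bytes <- as.integer(length_entry_bytes)
    t$name <- name
    t$n_batches <- as.integer(ceiling(n_rows / batch_size))
    t$payload <- matrix(0, n_rows, max_row_width * slot_cols)
    t$row_lengths <- integer(n_rows)
    t$dirty <- logical(t$n_batches)
    class(t) <- "FixedWidthTable"
    t
}

#' @export
print.FixedWidthTable <- function(x, ...) {
    cat(sprintf(
        "FixedWidthTable '%s': %d rows x %d slots (%d B/item), %d batches of %d rows, %d dirty\n",
        x$name, x$n_rows, x$max_row_width, x$item_bytes,
        x$n_batches, x$batch_size, sum(x$dirty)
    ))
    invisible(x)
}

#' Batch membership and byte accounting
#'
#' `rowBatch` maps a row to its batch; `batchRows` lists a batch's rows;
#' `batchBytes` is the modeled transfer size of one batch (payload plus its
#' slice of the row-length vector, so a flush unit is self-contained);
#' `tableBytesFull` is the full-table equivalent.
#'
#' @param table a `FixedWidthTable`.
#' @param row_index,batch_index 1-based indices.
#' @return Integer index / vector / byte count.
#' @export
rowBatch <- function(table, row_index) {
    ((as.integer(row_index) - 1L) %/% table$batch_size) + 1L
}

#' @rdname rowBatch
#' @export
batchRows <- function(table, batch_index) {
    lo <- (as.integer(batch_index) - 1L) * table$batch_size + 1L
    lo:min(lo + table$batch_size - 1L, table$n_rows)
}

#' @rdname rowBatch
#' @export
batchBytes <- function(table, batch_index) {
    nr <- length(batchRows(table, batch_index))
    nr * (table$max_row_width * table$item_bytes + table$length_entry_bytes)
}

#' @rdname rowBatch
#' @export
tableBytesFull <- function(table) {
    table$n_rows * (table$max_row_width * table$item_bytes +
                        table$length_entry_bytes)
}

#' Write one row
#'
#' Replaces the content and length of `row_index` and marks its batch dirty;
#' no other row or batch is touched.  Unused trailing slots are zero-filled
#' for reproducible serialization (consumers must still honor row_lengths).
#' A row longer than the fixed capacity raises an overflow error carrying
#' the row index, and leaves the table unchanged.
#'
#' @param table a `FixedWidthTable`.
#' @param row_index 1-based row.
#' @param items length-L vector (slot_cols = 1) or L x slot_cols matrix; L
#'   may be 0 to clear the row.
#' @return The table, invisibly.
#' @export
writeRow <- function(table, row_index, items) {
    r <- as.integer(row_index)
    if (r < 1 || r > table$n_rows) {
        stop(softcutError(sprintf("row index %d out of range", r),
                          "softcutArgumentError"))
    }
    m <- if (is.matrix(items)) items else
        matrix(items, ncol = table$slot_cols, byrow = TRUE)
    L <- nrow(m)
    if (L > table$max_row_width) {
        overflowError(r, table$name, L, table$max_row_width)
    }
    row <- numeric(table$max_row_width * table$slot_cols)
    if (L > 0) row[seq_len(L * table$slot_cols)] <- as.numeric(t(m))
    table$payload[r, ] <- row
    table$row_lengths[r] <- L
    table$dirty[rowBatch(table, r)] <- TRUE
    invisible(table)
}

#' Read one row
#'
#' @param table a `FixedWidthTable`.
#' @param row_index 1-based row.
#' @return Numeric vector (slot_cols = 1) or L x slot_cols matrix of the
#'   row's current items; length 0 / 0 rows when the row is empty.
#' @export
readRow <- function(table, row_index) {
    r <- as.integer(row_index)
    L <- table$row_lengths[r]
    v <- table$payload[r, seq_len(L * table$slot_cols)]
    if (table$slot_cols == 1L) v else matrix(v, ncol = table$slot_cols, byrow = TRUE)
}

#' Flush dirty batches
#'
#' Returns the transfer plan (one entry per dirty batch with its modeled
#' byte count) and clears all dirty flags.  When a ledger is given, the
#' frame's transfer record is appended: `bytes_batched` is the plan total
#' under batched transfers, or the full table size if anything was dirty
#' when `batching = FALSE` (whole-array copy policy); `bytes_full` is always
#' the full table size.
#'
#' @param table a `FixedWidthTable`.
#' @param ledger optional [newLedger()] to record into.
#' @param frame frame number for the ledger record.
#' @param batching logical; FALSE models whole-table copies on any edit.
#' @return Data frame with columns `batch` and `bytes` (the plan).
#' @export
flushTable <- function(table, ledger = NULL, frame = NA_integer_,
                       batching = TRUE) {
    dirty <- which(table$dirty)
    plan <- data.frame(
        batch = dirty,
        bytes = vapply(dirty, function(b) batchBytes(table, b), numeric(1))
    )
    table$dirty[] <- FALSE
    if (!is.null(ledger)) {
        full <- tableBytesFull(table)
        batched <- if (batching) sum(plan$bytes)
                   else if (length(dirty) > 0) full else 0
        recordTransfer(ledger, frame, table$name, batched, full, length(dirty))
    }
    plan
}

#' Host-side mirror of a table (the modeled device copy)
#'
#' `makeMirror` snapshots the table (the initial full upload);
#' `applyFlush` copies exactly the batches in a flush plan.  After any
#' sequence of writes and flushes, a mirror that applied every plan equals
#' the source table on all rows.
#'
#' @param table a `FixedWidthTable`.
#' @param mirror a mirror created by `makeMirror`.
#' @param plan a plan returned by [flushTable()].
#' @return The mirror (an environment with `payload` and `row_lengths`).
#' @export
makeMirror <- function(table) {
    m <- new.env(parent = emptyenv())
    m$payload <- table$payload
    m$row_lengths <- table$row_lengths
    class(m) <- "TableMirror"
    m
}

#' @rdname makeMirror
#' @export
applyFlush <- function(mirror, table, plan) {
    for (b in plan$batch) {
        rows <- batchRows(table, b)
        mirror$payload[rows, ] <- table$payload[rows, , drop = FALSE]
        mirror$row_lengths[rows] <- table$row_lengths[rows]
    }
    invisible(mirror)
}

# transfer ledger ------------------------------------------------------------

#' Create a transfer ledger
#'
#' Accumulates per-frame, per-table records of modeled transfer bytes:
#' `bytes_batched` (what a batched mirror copy shipped) vs `bytes_full`
#' (what copying the entire table would ship).
#'
#' @return An environment of class `TransferLedger`.
#' @export
newLedger <- function() {
    l <- new.env(parent = emptyenv())
    l$frame <- integer(0)
    l$table <- character(0)
    l$bytes_batched <- numeric(0)
    l$bytes_full <- numeric(0)
    l$n_dirty <- integer(0)
    class(l) <- "TransferLedger"
    l
}

recordTransfer <- function(ledger, frame, table_name, batched, full, n_dirty) {
    ledger$frame <- c(ledger$frame, as.integer(frame))
    ledger$table <- c(ledger$table, table_name)
    ledger$bytes_batched <- c(ledger$bytes_batched, batched)
    ledger$bytes_full <- c(ledger$bytes_full, full)
    ledger$n_dirty <- c(ledger$n_dirty, as.integer(n_dirty))
    invisible(ledger)
}

#' @export
as.data.frame.TransferLedger <- function(x, ...) {
    data.frame(
        frame = x$frame,
        table_name = x$table,
        bytes_batched = x$bytes_batched,
        bytes_full = x$bytes_full,
        n_dirty_batches = x$n_dirty,
        stringsAsFactors = FALSE
    )
}

#' @export
print.TransferLedger <- function(x, ...) {
    cat(sprintf(
        "TransferLedger: %d records over %d frames\n",
        length(x$frame), length(unique(x$frame))
    ))
    invisible(x)
}

#' Frames in which any table was edited
#'
#' @param ledger a `TransferLedger`.
#' @return Sorted integer vector of frames with at least one dirty batch.
#' @export
editedFrames <- function(ledger) {
    sort(unique(ledger$frame[ledger$n_dirty > 0]))
}

#' Transfer-reduction report
#'
#' Reduction = 1 - sum(bytes_batched) / sum(bytes_full) over the selected
#' frames, per table and aggregate.  A run with zero edits gives 1 (nothing
#' transferred under the edit-only policy); rewriting every row every frame
#' gives 0.
#'
#' @param ledger a `TransferLedger`.
#' @param frames frames to include (default: all recorded frames).
#' @return List with `aggregate` (scalar in \[0, 1\]), `per_table` (data
#'   frame with columns table_name, bytes_batched, bytes_full, reduction)
#'   and `frames`.
#' @export
reductionReport <- function(ledger, frames = NULL) {
    df <- as.data.frame(ledger)
    if (is.null(frames)) frames <- unique(df$frame)
    df <- df[df$frame %in% frames, , drop = FALSE]
    if (nrow(df) == 0) {
        stop(softcutError("no ledger records in the requested frame range",
                          "softcutArgumentError"))
    }
    agg <- 1 - sum(df$bytes_batched) / sum(df$bytes_full)
    per <- do.call(rbind, lapply(split(df, df$table_name), function(d) {
        data.frame(
            table_name = d$table_name[1],
            bytes_batched = sum(d$bytes_batched),
            bytes_full = sum(d$bytes_full),
            reduction = 1 - sum(d$bytes_batched) / sum(d$bytes_full),
            stringsAsFactors = FALSE
        )
    }))
    rownames(per) <- NULL
    list(aggregate = agg, per_table = per, frames = sort(frames))
}

#' Write / read the ledger CSV
#'
#' Columns: frame, table_name, bytes_batched, bytes_full, n_dirty_batches.
#'
#' @param ledger a `TransferLedger`.
#' @param path CSV path.
#' @return `readLedgerCSV` returns a `TransferLedger`.
#' @export
writeLedgerCSV <- function(ledger, path) {
    write.csv(as.data.frame(ledger), path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeLedgerCSV
#' @export
readLedgerCSV <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    l <- newLedger()
    l$frame <- as.integer(df$frame)
    l$table <- as.character(df$table_name)
    l$bytes_batched <- as.numeric(df$bytes_batched)
    l$bytes_full <- as.numeric(df$bytes_full)
    l$n_dirty <- as.integer(df$n_dirty_batches)
    l
}

#' Serialize / restore a table snapshot as plain text
#'
#' Versioned text format (`SOFTCUT-TABLE 1`) carrying the table geometry and
#' the occupied items of every row; used for fixtures and debugging.
#'
#' @param table a `FixedWidthTable`.
#' @param path file path.
#' @return `readTableSnapshot` returns a `FixedWidthTable` (all clean).
#' @export
writeTableSnapshot <- function(table, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("SOFTCUT-TABLE 1", con)
    writeLines(sprintf("%s %d %d %d %d %d", table$name, table$n_rows,
                       table$max_row_width, table$item_bytes,
                       table$batch_size, table$slot_cols), con)
    for (r in seq_len(table$n_rows)) {
        L <- table$row_lengths[r]
        v <- table$payload[r, seq_len(L * table$slot_cols)]
        writeLines(paste(c(L, format(v, digits = 17)), collapse = " "), con)
    }
    invisible(path)
}

#' @rdname writeTableSnapshot
#' @export
readTableSnapshot <- function(path) {
    lines <- readLines(path)
    if (lines[1] != "SOFTCUT-TABLE 1") {
        stop(softcutError("not a SOFTCUT-TABLE 1 file", "softcutFormatError"))
    }
    hdr <- strsplit(lines[2], " ")[[1]]
    t <- createTable(as.integer(hdr[2]), as.integer(hdr[3]),
                     as.integer(hdr[4]), as.integer(hdr[5]),
                     name = hdr[1], slot_cols = as.integer(hdr[6]))
    for (r in seq_len(t$n_rows)) {
        v <- as.numeric(strsplit(lines[2 + r], " +")[[1]])
        L <- as.integer(v[1])
        if (L > 0) {
            writeRow(t, r, matrix(v[-1], ncol = t$slot_cols, byrow = TRUE))
        }
    }
    t$dirty[] <- FALSE
    t
}
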