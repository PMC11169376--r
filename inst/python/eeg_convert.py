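#!/usr/bin/env python
"""Convert DEAP / DREAMER subject containers to a plain interchange bundle.

The bundle is a pair of files <out>.json (metadata: subject, sampling rate,
channel names, per-trial sample counts and ratings) and <out>.bin
(float64 little-endian, trials concatenated, each trial stored channel by
channel). The R package reads this bundle; this script exists because the
source containers are Python pickles (DEAP) and MATLAB files (DREAMER).
"""
import argparse
import json
import pickle
import sys

import numpy as np

DEAP_CHANNELS = [
    "Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5", "CP1", "P3",
    "P7", "PO3", "O1", "Oz", "Pz", "Fp2", "AF4", "Fz", "F4", "F8", "FC6",
    "FC2", "Cz", "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2",
]
DREAMER_CHANNELS = [
    "AF3", "F7", "F3", "FC5", "T7", "P7", "O1", "O2", "P8", "T8", "FC6",
    "F4", "F8", "AF4",
]


def fail(msg):
    sys.stderr.write("eeg_convert: " + msg + "\n")
    sys.exit(2)


def convert_deap(path, subject_id):
    with open(path, "rb") as fh:
        obj = pickle.load(fh, encoding="latin1")
    try:
        data = np.asarray(obj["data"], dtype=np.float64)
        labels = np.asarray(obj["labels"], dtype=np.float64)
    except Exception:
        fail("not a DEAP preprocessed container (needs 'data' and 'labels')")
    if data.ndim != 3 or data.shape[1] < 32:
        fail("dialect error: DEAP expects trials x >=32 channels x samples, "
             "got shape %s" % (data.shape,))
    if labels.shape[0] != data.shape[0] or labels.shape[1] < 3:
        fail("dialect error: DEAP labels must be trials x >=3 ratings")
    trials = []
    sigs = []
    for i in range(data.shape[0]):
        sig = data[i, :32, :]  # EEG rows only; peripheral channels ignored
        sigs.append(sig)
        trials.append({
            "trial_id": i + 1,
            "n_samples": int(sig.shape[1]),
            "ratings": {
                "valence": float(labels[i, 0]),
                "arousal": float(labels[i, 1]),
                "dominance": float(labels[i, 2]),
            },
        })
    meta = {"subject_id": subject_id, "fs": 128, "dialect": "deap",
            "channel_names": DEAP_CHANNELS, "trials": trials}
    return meta, sigs


def convert_dreamer(path, subject_index, subject_id):
    from scipy.io import loadmat
    m = loadmat(path, squeeze_me=True, struct_as_record=False)
    if "DREAMER" not in m:
        fail("not a DREAMER container (no 'DREAMER' variable)")
    root = m["DREAMER"]
    data = np.atleast_1d(root.Data)
    if subject_index < 1 or subject_index > data.size:
        fail("subject index %d out of range 1..%d" % (subject_index, data.size))
    sub = data[subject_index - 1]
    stim = np.atleast_1d(sub.EEG.stimuli)
    val = np.atleast_1d(sub.ScoreValence)
    aro = np.atleast_1d(sub.ScoreArousal)
    dom = np.atleast_1d(sub.ScoreDominance)
    trials = []
    sigs = []
    for i in range(stim.size):
        sig = np.asarray(stim[i], dtype=np.float64)
        if sig.ndim != 2:
            fail("dialect error: DREAMER stimulus %d is not a 2-D array" % (i + 1))
        if sig.shape[1] == 14:  # stored time x channels
            sig = sig.T
        if sig.shape[0] != 14:
            fail("dialect error: DREAMER expects 14 channels, got %d"
                 % min(sig.shape))
        sigs.append(sig)
        trials.append({
            "trial_id": i + 1,
            "n_samples": int(sig.shape[1]),
            "ratings": {
                "valence": float(val[i]),
                "arousal": float(aro[i]),
                "dominance": float(dom[i]),
            },
        })
    meta = {"subject_id": subject_id, "fs": 128, "dialect": "dreamer",
            "channel_names": DREAMER_CHANNELS, "trials": trials}
    return meta, sigs


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--input", required=True)
    ap.add_argument("--dialect", required=True, choices=["deap", "dreamer"])
    ap.add_argument("--subject", type=int, default=1,
                    help="1-based subject index (DREAMER containers hold all subjects)")
    ap.add_argument("--subject-id", default=None)
    ap.add_argument("--out", required=True, help="output path prefix")
    args = ap.parse_args()

    sid = args.subject_id or ("s%02d" % args.subject)
    if args.dialect == "deap":
        meta, sigs = convert_deap(args.input, sid)
    else:
        meta, sigs = convert_dreamer(args.input, args.subject, sid)

    with open(args.out + ".json", "w") as fh:
        json.dump(meta, fh)
    with open(args.out + ".bin", "wb") as fh:
        for sig in sigs:
            np.ascontiguousarray(sig, dtype="<f8").tofile(fh)


if __name__ == "__main__":
    main()
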