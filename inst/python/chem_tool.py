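"""Batch chemistry helper: one JSON request per stdin line, one JSON reply per stdout line.

Usage: python chem_tool.py <op>
Ops: canon | random | match | hassub | scaffold
"""
import sys
import json
import random

from rdkit import Chem, RDLogger
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")


def parse(smiles):
    """Return (mol, reason). Distinguishes syntax failure from sanitization failure."""
    mol = Chem.MolFromSmiles(smiles, sanitize=False)
    if mol is None:
        return None, "parse_error"
    try:
        Chem.SanitizeMol(mol)
    except Exception:
        return None, "sanitize_error"
    return mol, None


def largest_organic_fragment(mol):
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    if len(frags) <= 1:
        return mol

    def key(f):
        has_c = any(a.GetAtomicNum() == 6 for a in f.GetAtoms())
        return (has_c, f.GetNumHeavyAtoms())

    return max(frags, key=key)


def op_canon(req):
    mol, reason = parse(req["s"])
    if mol is None:
        return {"ok": False, "reason": reason}
    mol = largest_organic_fragment(mol)
    mol = Chem.RemoveHs(mol)
    return {"ok": True, "canonical": Chem.MolToSmiles(mol)}


def op_random(req):
    mol, reason = parse(req["s"])
    if mol is None:
        return {"ok": False, "reason": reason}
    n, seed = int(req["n"]), int(req["seed"])
    natoms = mol.GetNumAtoms()
    out = []
    for i in range(n):
        rng = random.Random(seed * 1000003 + i)
        perm = list(range(natoms))
        rng.shuffle(perm)
        out.append(Chem.MolToSmiles(Chem.RenumberAtoms(mol, perm), canonical=False))
    return {"ok": True, "out": out}


def op_match(req):
    mol, reason = parse(req["s"])
    if mol is None:
        return {"ok": False, "reason": reason}
    res = {}
    for name, smarts in req["patterns"].items():
        patt = Chem.MolFromSmarts(smarts)
        if patt is None:
            res[name] = None
            continue
        res[name] = [list(m) for m in mol.GetSubstructMatches(patt)]
    return {"ok": True, "matches": res}


def op_hassub(req):
    mol, reason = parse(req["s"])
    if mol is None:
        return {"ok": False, "reason": reason}
    if req.get("smarts", False):
        patt = Chem.MolFromSmarts(req["q"])
    else:
        patt = Chem.MolFromSmiles(req["q"])
    if patt is None:
        return {"ok": False, "reason": "bad_query"}
    return {"ok": True, "has": mol.HasSubstructMatch(patt)}


def op_scaffold(req):
    mol, reason = parse(req["s"])
    if mol is None:
        return {"ok": False, "reason": reason}
    scaf = MurckoScaffold.GetScaffoldForMol(mol)
    return {"ok": True, "scaffold": Chem.MolToSmiles(scaf)}


OPS = {
    "canon": op_canon,
    "random": op_random,
    "match": op_match,
    "hassub": op_hassub,
    "scaffold": op_scaffold,
}


def main():
    op = OPS[sys.argv[1]]
    for line in sys.stdin:
        line = line.strip()
        if not line:
            continue
        try:
            reply = op(json.loads(line))
        except Exception as exc:  # never kill the batch on one record
            reply = {"ok": False, "reason": "internal:" + type(exc).__name__}
        sys.stdout.write(json.dumps(reply) + "\n")


if __name__ == "__main__":
    main()
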