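"""Batch cheminformatics bridge.

Reads a JSON request on stdin:  {"task": "...", "smiles": ["CCO", ...]}
and writes a JSON response on stdout.  Tasks:

  graphs       -> heavy-atom molecular graphs (atomic numbers, labeled bonds)
  maccs        -> 166-bit MACCS structural keys (keys 1..166)
  descriptors  -> the full RDKit 2D descriptor collection, unfiltered

Per-molecule failures are reported as {"ok": false, "error": ...} so the
caller can name the offending row; the process itself always exits 0 on a
well-formed request.
"""

import json
import math
import sys

from rdkit import Chem
from rdkit import RDLogger
from rdkit.Chem import Descriptors, MACCSkeys

RDLogger.DisableLog("rdApp.*")

BOND_LABELS = {
    Chem.BondType.SINGLE: "single",
    Chem.BondType.DOUBLE: "double",
    Chem.BondType.TRIPLE: "triple",
    Chem.BondType.AROMATIC: "aromatic",
}


def _mol(smiles):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None or mol.GetNumAtoms() == 0:
        return None
    return mol


def task_graphs(smiles_list):
    out = []
    for smi in smiles_list:
        mol = _mol(smi)
        if mol is None:
            out.append({"ok": False, "error": "unparseable SMILES"})
            continue
        atoms = [a.GetAtomicNum() for a in mol.GetAtoms()]
        bonds = []
        bad = None
        for b in mol.GetBonds():
            lab = BOND_LABELS.get(b.GetBondType())
            if lab is None:
                bad = "unsupported bond type %s" % b.GetBondType()
                break
            # 1-based endpoints for the R side
            bonds.append([b.GetBeginAtomIdx() + 1, b.GetEndAtomIdx() + 1, lab])
        if bad is not None:
            out.append({"ok": False, "error": bad})
        else:
            out.append({"ok": True, "atoms": atoms, "bonds": bonds})
    return out


def task_maccs(smiles_list):
    out = []
    for smi in smiles_list:
        mol = _mol(smi)
        if mol is None:
            out.append({"ok": False, "error": "unparseable SMILES"})
            continue
        fp = MACCSkeys.GenMACCSKeys(mol)  # 167 bits, bit 0 unused
        out.append({"ok": True, "bits": [int(fp.GetBit(i)) for i in range(1, 167)]})
    return out


def task_descriptors(smiles_list):
    names = [n for n, _ in Descriptors.descList]
    out = []
    for smi in smiles_list:
        mol = _mol(smi)
        if mol is None:
            out.append({"ok": False, "error": "unparseable SMILES"})
            continue
        vals = []
        try:
            for _, fn in Descriptors.descList:
                v = fn(mol)
                if isinstance(v, bool):
                    vals.append(None)  # boolean-typed: treated as non-numeric
                elif v is None or (isinstance(v, float) and not math.isfinite(v)):
                    vals.append(None)
                else:
                    vals.append(float(v))
        except Exception as exc:  # descriptor engine failure on this molecule
            out.append({"ok": False, "error": str(exc)})
            continue
        out.append({"ok": True, "values": vals})
    return {"names": names, "results": out}


def main():
    req = json.load(sys.stdin)
    task = req["task"]
    smiles = req["smiles"]
    if task == "graphs":
        resp = {"results": task_graphs(smiles)}
    elif task == "maccs":
        resp = {"results": task_maccs(smiles)}
    elif task == "descriptors":
        resp = task_descriptors(smiles)
    else:
        raise SystemExit("unknown task: %r" % task)
    json.dump(resp, sys.stdout)


if __name__ == "__main__":
    main()
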