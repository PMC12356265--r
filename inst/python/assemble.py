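"""Merge labeled SMILES fragments into canonical structures.

Reads a JSON object {"jobs": [[smiles, ...], ...]} on stdin. Each job is a
list of SMILES fragments carrying atom-map labels on shared atoms; atoms
with equal map numbers across fragments are unified into a single atom that
inherits the union of their bonds. Hydrogens on merged atoms are re-derived
from standard valence after the merge; over-valence is a hard error for the
job. Empty fragment strings contribute nothing (an "absent" submodule).

Writes a JSON array to stdout, one object per job:
  {"smiles": canonical SMILES or null,
   "formula": Hill molecular formula or null,
   "natoms": heavy-atom count or null,
   "error": null or a message}
"""
import json
import sys

from rdkit import Chem
from rdkit.Chem import rdMolDescriptors
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def merge(frags):
    mols = []
    for s in frags:
        if isinstance(s, list):  # length-1 JSON arrays from strict encoders
            s = s[0] if s else ""
        if not s:
            continue
        m = Chem.MolFromSmiles(s, sanitize=True)
        if m is None:
            raise ValueError("unparseable fragment: %s" % s)
        mols.append(m)
    if not mols:
        raise ValueError("no non-empty fragments")
    combo = mols[0]
    for m in mols[1:]:
        combo = Chem.CombineMols(combo, m)
    rw = Chem.RWMol(combo)
    groups = {}
    for a in rw.GetAtoms():
        n = a.GetAtomMapNum()
        if n:
            groups.setdefault(n, []).append(a.GetIdx())
    remove = []
    for n, idxs in groups.items():
        keep = idxs[0]
        ka = rw.GetAtomWithIdx(keep)
        for d in idxs[1:]:
            da = rw.GetAtomWithIdx(d)
            if da.GetSymbol() != ka.GetSymbol():
                raise ValueError(
                    "label %d would merge %s with %s"
                    % (n, ka.GetSymbol(), da.GetSymbol())
                )
            for b in da.GetBonds():
                o = b.GetOtherAtom(da).GetIdx()
                o_keep = o
                for idxs2 in groups.values():
                    if o in idxs2[1:]:
                        o_keep = idxs2[0]
                if o_keep == keep:
                    continue
                if rw.GetBondBetweenAtoms(keep, o_keep) is None:
                    rw.AddBond(keep, o_keep, b.GetBondType())
            remove.append(d)
    unmatched = [n for n, idxs in groups.items() if len(idxs) == 1]
    for d in sorted(remove, reverse=True):
        rw.RemoveAtom(d)
    for a in rw.GetAtoms():
        if a.GetAtomMapNum():
            # shared atom: hydrogens re-derived from standard valence
            a.SetAtomMapNum(0)
            a.SetNumExplicitHs(0)
            a.SetNumRadicalElectrons(0)
            a.SetNoImplicit(False)
    mol = rw.GetMol()
    try:
        Chem.SanitizeMol(mol)
    except Exception as e:  # valence violation after merge
        raise ValueError("merge produced an invalid structure: %s" % e)
    return (
        Chem.MolToSmiles(mol),
        rdMolDescriptors.CalcMolFormula(mol),
        mol.GetNumAtoms(),
        sorted(unmatched),
    )


def main():
    payload = json.load(sys.stdin)
    out = []
    for frags in payload["jobs"]:
        try:
            smi, formula, natoms, unmatched = merge(frags)
            out.append(
                {
                    "smiles": smi,
                    "formula": formula,
                    "natoms": natoms,
                    "unmatched": unmatched,
                    "error": None,
                }
            )
        except Exception as e:
            out.append(
                {
                    "smiles": None,
                    "formula": None,
                    "natoms": None,
                    "unmatched": [],
                    "error": str(e),
                }
            )
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
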