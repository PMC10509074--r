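"""Batch 3D embedding of ligands with seeded ETKDG.

Reads a tab-separated file with columns id, smiles, seed (one molecule per
line, no header) and writes an SDF of heavy-atom 3D conformers. Each molecule
is embedded with its own integer seed so results are reproducible molecule by
molecule. Formal charges are emitted as a space-separated SD tag
(<atom_charges>) because V2000 M CHG lines are not retained by every reader.
Molecules that fail to parse or embed are skipped; their ids are written to
stderr as 'FAILED <id>'.
"""

import sys
import argparse

from rdkit import Chem
from rdkit.Chem import AllChem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def embed_one(smiles, seed):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return None
    molh = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = int(seed)
    if AllChem.EmbedMolecule(molh, params) != 0:
        params.useRandomCoords = True
        if AllChem.EmbedMolecule(molh, params) != 0:
            return None
    return Chem.RemoveHs(molh)


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--infile", required=True)
    ap.add_argument("--outfile", required=True)
    args = ap.parse_args()

    writer = Chem.SDWriter(args.outfile)
    n_ok = 0
    with open(args.infile) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line.strip():
                continue
            lig_id, smiles, seed = line.split("\t")
            mol = embed_one(smiles, seed)
            if mol is None:
                sys.stderr.write("FAILED %s\n" % lig_id)
                continue
            mol.SetProp("_Name", lig_id)
            mol.SetProp("smiles", smiles)
            mol.SetProp(
                "atom_charges",
                " ".join(str(a.GetFormalCharge()) for a in mol.GetAtoms()),
            )
            writer.write(mol)
            n_ok += 1
    writer.close()
    sys.stderr.write("EMBEDDED %d\n" % n_ok)


if __name__ == "__main__":
    main()
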