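"""Conformer generation backend: seeded distance-geometry embedding (ETKDG)
followed by MMFF94 minimization (UFF fallback).

Usage: python gen_conformers.py <in.smi> <out.sdf> <budget> <seed>

Input: one 'SMILES id' per line. Output: multi-record SDF, one record per
conformer, with <mol_id> and <energy_kcal> data fields. Deterministic for a
fixed seed. Embedding failures are reported as '#FAIL <id> <reason>' lines
on stdout and the molecule is omitted from the SDF.
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def main(in_smi, out_sdf, budget, seed):
    writer = Chem.SDWriter(out_sdf)
    with open(in_smi) as fh:
        for line in fh:
            parts = line.split()
            if not parts:
                continue
            smi = parts[0]
            mol_id = parts[1] if len(parts) > 1 else smi
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                print("#FAIL", mol_id, "unparseable")
                continue
            mol = Chem.AddHs(mol)
            params = AllChem.ETKDGv3()
            params.randomSeed = seed
            params.pruneRmsThresh = 0.15
            params.useRandomCoords = False
            cids = AllChem.EmbedMultipleConfs(mol, numConfs=budget,
                                              params=params)
            if len(cids) == 0:
                # deterministic fallback for hard geometries
                params.useRandomCoords = True
                params.maxIterations = 500
                cids = AllChem.EmbedMultipleConfs(mol, numConfs=budget,
                                                  params=params)
            if len(cids) == 0:
                print("#FAIL", mol_id, "embedding-failed")
                continue
            try:
                res = AllChem.MMFFOptimizeMoleculeConfs(mol, maxIters=1000)
                if any(e is None for _, e in res):
                    raise ValueError("MMFF energy missing")
            except Exception:
                res = AllChem.UFFOptimizeMoleculeConfs(mol, maxIters=1000)
            mol.SetProp("mol_id", mol_id)
            for cid, (_, energy) in zip(cids, res):
                mol.SetProp("energy_kcal", repr(float(energy)))
                writer.write(mol, confId=cid)
    writer.close()


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2], int(sys.argv[3]), int(sys.argv[4]))
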