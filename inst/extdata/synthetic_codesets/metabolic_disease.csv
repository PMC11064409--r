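code,description
E70,Disorders of aromatic amino-acid metabolism (synthetic placeholder entry)
E71,Disorders of branched-chain amino-acid and fatty-acid metabolism (synthetic placeholder entry)
E72,Other disorders of amino-acid metabolism (synthetic placeholder entry)
E74,Other disorders of carbohydrate metabolism (synthetic placeholder entry)
E75,Disorders of sphingolipid metabolism (synthetic placeholder entry)
E76,Disorders of glycosaminoglycan metabolism (synthetic placeholder entry)
E88.4,Mitochondrial metabolism disorders (synthetic placeholder entry)
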