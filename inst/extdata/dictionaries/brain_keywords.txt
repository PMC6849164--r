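# Dict1: brain-related keywords for the paired brain-metastasis model.
brain
cerebral
cerebellar
intracranial
parenchymal
frontal lobe
occipital lobe
temporal lobe
parietal lobe
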