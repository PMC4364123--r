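numeral,name,source
I,"Sylvian Fissure",printed
II,"Central Sulcus",printed
III,"Postcentral Sulcus",printed
IV,"Precentral Sulcus",printed
V,"Superior Temporal Sulcus",printed
VI,"Superior Frontal Sulcus",reconstructed
VII,"Intraparietal Sulcus",printed
VIII,"Primary Intermediate Sulcus",printed
IX,"Secondary Intermediate Sulcus",printed
X,"Transverse Occipital Sulcus",printed
XI,"Inferior Temporal Sulcus",printed
XII,"Inferior Frontal Sulcus",printed
XIII,"Middle Frontal Sulcus",printed
XIV,"Olfactory Sulcus",printed
XV,"Occipital-Temporal Sulcus",printed
XVI,"Collateral Sulcus",printed
XVII,"Olfactory Control Line",printed
XVIII,"Olfactory-Middle Frontal Control Line",printed
XIX,"Middle Frontal-Precentral Control Line",printed
XX,"Precentral-Central Control Line",printed
XXI,"Central-Postcentral Control Line",printed
XXII,"Postcentral-Transverse Occipital Control Line",printed
XXIII,"Occipital Control Line",printed
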