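species,mass_kg,migratory,domestic
wildebeest,123,TRUE,FALSE
zebra,200,TRUE,FALSE
thomsons_gazelle,15,FALSE,FALSE
impala,40,FALSE,FALSE
topi,100,FALSE,FALSE
grants_gazelle,40,FALSE,FALSE
buffalo,450,FALSE,FALSE
eland,340,FALSE,FALSE
hartebeest,117,FALSE,FALSE
giraffe,825,FALSE,FALSE
warthog,45,FALSE,FALSE
elephant,1725,FALSE,FALSE
waterbuck,160,FALSE,FALSE
hippopotamus,1000,FALSE,FALSE
rhinoceros,816,FALSE,FALSE
reedbuck,35,FALSE,FALSE
bushbuck,30,FALSE,FALSE
oribi,10,FALSE,FALSE
dikdik,4,FALSE,FALSE
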