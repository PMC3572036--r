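(((((((((((Human,Chimp),Gorilla),Orangutan),Rhesus),Marmoset),Tarsier),(MouseLemur,Bushbaby)),TreeShrew),(((((Mouse,Rat),KangarooRat),GuineaPig),Squirrel),(Rabbit,Pika))),((((Cow,Dolphin),Alpaca),((Horse,(Cat,Dog)),(Microbat,Megabat))),(Hedgehog,Shrew))),(((Elephant,RockHyrax),Tenrec),(Sloth,Armadillo)));
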